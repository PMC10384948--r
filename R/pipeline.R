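#' Pipeline configuration
#'
#' The whole workflow is driven by one nested configuration (YAML on
#' disk): `io` paths, `align`/`annotation` tolerances, `filters`
#' thresholds, `plsda`, `sae` and `evaluation` hyperparameters, the
#' `synthetic` cohort section and a single global `seed` from which every
#' stage seed is derived deterministically. Unknown keys are rejected so
#' typos fail loudly, and a config survives a load/dump/load round trip
#' unchanged.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    io = list(output_dir = "fnacmet_output", peaklist_dir = "",
              metadata = "", compound_table = ""),
    align = list(mz_tol_ppm = 10, rt_tol_min = 1.0),
    annotation = list(tol_ppm = 15),
    filters = list(min_mean_intensity = 1e4, min_blank_ratio = 50,
                   require_adduct_annotation = TRUE,
                   require_evidence_flag = FALSE),
    plsda = list(A_max = 5, folds = 10, n_perm = 200),
    sae = list(hidden_sizes = 64L, latent_dim = 2L, recon_weight = 0.1,
               learning_rate = 1e-3, epochs = 300L, batch_size = 16L),
    select = list(k = 15L, drop_fraction = 0.5),
    evaluation = list(n_repeats = 4L, test_fraction = 0.25),
    synthetic = list(enabled = TRUE, n_benign = 56L, n_malignant = 22L,
                     n_blanks = 6L, n_qc = 3L, n_features_pos = 500L,
                     n_features_neg = 200L, n_informative = 15L,
                     bio_cv = 0.35, blank_contamination_fraction = 0.25,
                     below_intensity_fraction = 0.30,
                     annotatable_fraction = 0.45))
}

check_config_keys <- function(config, reference, path = "") {
  unknown <- setdiff(names(config), names(reference))
  if (length(unknown))
    abort_validation("unknown config key(s): %s",
                     paste0(path, unknown, collapse = ", "))
  for (k in names(config))
    if (is.list(reference[[k]]) && !is.null(names(reference[[k]])))
      check_config_keys(as.list(config[[k]]), reference[[k]],
                        paste0(path, k, "."))
  invisible(TRUE)
}

merge_config <- function(config, reference) {
  for (k in names(reference)) {
    if (is.null(config[[k]])) {
      config[[k]] <- reference[[k]]
    } else if (is.list(reference[[k]]) && !is.null(names(reference[[k]]))) {
      config[[k]] <- merge_config(as.list(config[[k]]), reference[[k]])
    }
  }
  config[names(reference)]
}

#' Read, complete and validate a pipeline configuration
#' @param path YAML file; when `NULL` the defaults are returned.
#' @return Validated config list.
#' @export
read_config <- function(path = NULL) {
  ref <- default_config()
  if (is.null(path)) return(ref)
  config <- yaml::read_yaml(path)
  check_config_keys(config, ref)
  merge_config(config, ref)
}

#' Write a configuration as YAML
#' @param config Config list.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

synthetic_spec_from_config <- function(config) {
  s <- config$synthetic
  cohort_spec(n_benign = s$n_benign, n_malignant = s$n_malignant,
              n_blanks = s$n_blanks, n_qc = s$n_qc,
              n_features_pos = s$n_features_pos,
              n_features_neg = s$n_features_neg,
              n_informative = s$n_informative,
              bio_cv = s$bio_cv,
              blank_contamination_fraction =
                s$blank_contamination_fraction,
              below_intensity_fraction = s$below_intensity_fraction,
              annotatable_fraction = s$annotatable_fraction,
              seed = derive_seed(config$seed, 1L))
}

sae_config_from_config <- function(config, seed_index = 6L) {
  s <- config$sae
  sae_config(hidden_sizes = s$hidden_sizes, latent_dim = s$latent_dim,
             recon_weight = s$recon_weight,
             learning_rate = s$learning_rate, epochs = s$epochs,
             batch_size = s$batch_size,
             seed = derive_seed(config$seed, seed_index))
}

#' Read a cohort from disk (peak-list CSVs plus a metadata JSON)
#'
#' The metadata JSON is an array of records with fields `path`, `run_id`,
#' `role`, `mode`, `class_label`; paths are resolved relative to the
#' metadata file.
#'
#' @param metadata_path Path to the metadata JSON.
#' @return List of [peak_list] objects.
#' @export
read_cohort_peaklists <- function(metadata_path) {
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  base <- dirname(metadata_path)
  lapply(seq_len(nrow(meta)), function(i) {
    p <- meta$path[i]
    if (!file.exists(p)) p <- file.path(base, meta$path[i])
    read_peak_list(p, run_id = meta$run_id[i], role = meta$role[i],
                   mode = meta$mode[i], class_label = meta$class_label[i])
  })
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created).
#' @return The metadata JSON path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "peaklists"), recursive = TRUE,
             showWarnings = FALSE)
  meta <- data.frame(path = character(), run_id = character(),
                     role = character(), mode = character(),
                     class_label = character(), stringsAsFactors = FALSE)
  for (key in names(cohort$peak_lists)) {
    pl <- cohort$peak_lists[[key]]
    fn <- file.path("peaklists",
                    sprintf("%s_%s.csv", substr(pl$mode, 1, 3), pl$run_id))
    write_peak_list(pl, file.path(dir, fn))
    meta <- rbind(meta, data.frame(path = fn, run_id = pl$run_id,
                                   role = pl$role, mode = pl$mode,
                                   class_label = pl$class_label))
  }
  write_compound_table(cohort$compounds, file.path(dir, "compounds.tsv"))
  utils::write.csv(cohort$ground_truth,
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  mp <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, mp, dataframe = "rows", auto_unbox = FALSE)
  mp
}

#' Run the full pipeline
#'
#' Executes, in order: cohort simulation (or loading), per-mode join
#' alignment, mode merging, adduct annotation, the ion-selection cascade,
#' normalisation, top-down SAE signature selection and the four-model
#' comparison, writing every export plus a run manifest. The manifest
#' records the config hash, derived stage seeds, stage-by-stage
#' input/output counts and a checksum for every output file; it contains
#' no clock values, so two runs with the same config are bit-identical.
#'
#' @param config Config list from [read_config()] / [default_config()].
#' @param out_dir Output directory; defaults to `config$io$output_dir`.
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(),
                         out_dir = config$io$output_dir, quiet = FALSE) {
  check_config_keys(config, default_config())
  config <- merge_config(config, default_config())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage_counts <- list()
  outputs <- character(0)

  # stage 1: inputs
  if (isTRUE(config$synthetic$enabled)) {
    say("stage simulate: generating synthetic cohort")
    cohort <- generate_cohort(synthetic_spec_from_config(config))
    peak_lists <- cohort$peak_lists
    compounds <- cohort$compounds
    gt_path <- file.path(out_dir, "ground_truth.csv")
    utils::write.csv(cohort$ground_truth, gt_path, row.names = FALSE)
    outputs <- c(outputs, gt_path)
  } else {
    say("stage load: reading peak lists")
    peak_lists <- read_cohort_peaklists(config$io$metadata)
    compounds <- read_compound_table(config$io$compound_table)
    cohort <- NULL
  }
  stage_counts$input_runs <- length(peak_lists)

  # stage 2: alignment per mode, then merge
  modes <- vapply(peak_lists, `[[`, character(1), "mode")
  say("stage align: %d positive-mode and %d negative-mode runs",
      sum(modes == "positive"), sum(modes == "negative"))
  tab_pos <- join_align(peak_lists[modes == "positive"],
                        config$align$mz_tol_ppm, config$align$rt_tol_min)
  tab_neg <- if (any(modes == "negative"))
    join_align(peak_lists[modes == "negative"],
               config$align$mz_tol_ppm, config$align$rt_tol_min)
  else NULL
  merged <- if (is.null(tab_neg)) tab_pos else merge_modes(tab_pos, tab_neg)
  stage_counts$aligned_features <- nrow(merged$features)

  # stage 3: annotation
  say("stage annotate: %d features vs %d compounds",
      nrow(merged$features), nrow(compounds))
  annotations <- annotate(merged, compounds, config$annotation$tol_ppm)
  stage_counts$annotated_features <- length(unique(annotations$feature_id))

  # stage 4: filtering cascade
  say("stage filter: applying ion-selection cascade")
  fc <- filter_config(config$filters$min_mean_intensity,
                      config$filters$min_blank_ratio,
                      config$filters$require_adduct_annotation,
                      config$filters$require_evidence_flag)
  cascade <- apply_cascade(merged, annotations, fc)
  filtered <- cascade$table
  stage_counts$post_filter_features <- nrow(filtered$features)
  ft_path <- file.path(out_dir, "feature_table_filtered.csv")
  write_feature_table(filtered, ft_path)
  rep_path <- file.path(out_dir, "filter_report.json")
  write_filter_report(cascade$report, rep_path)
  outputs <- c(outputs, ft_path, paste0(ft_path, ".samples.json"), rep_path)

  # stage 5: normalisation
  say("stage normalize: standardised log10 intensities")
  norm <- normalize_intensities(filtered)
  X <- model_matrix_from_norm(norm)
  y <- norm$class_labels
  stage_counts$model_samples <- nrow(X)

  # stage 6: top-down signature selection
  say("stage select: top-down SAE selection to %d ions", config$select$k)
  sig <- topdown_select(X, y, k = config$select$k,
                        drop_fraction = config$select$drop_fraction,
                        config = sae_config_from_config(config),
                        table = filtered, annotations = annotations,
                        compounds = compounds)
  sig_path <- file.path(out_dir, "signature.csv")
  write_signature(sig, sig_path)
  outputs <- c(outputs, sig_path, sub("\\.csv$", ".json", sig_path))
  stage_counts$signature_size <- nrow(sig$entries)

  # stage 7: evaluation / model comparison on the signature
  say("stage evaluate: %d stratified repeats", config$evaluation$n_repeats)
  Xs <- X[, sig$entries$feature_id, drop = FALSE]
  plan <- make_splits(y, config$evaluation$n_repeats,
                      config$evaluation$test_fraction,
                      seed = derive_seed(config$seed, 7L))
  plan_path <- file.path(out_dir, "split_plan.json")
  write_split_plan(plan, plan_path)
  comparison <- compare_models(
    Xs, y, plan,
    registry = model_registry(sae_cfg = sae_config_from_config(config, 8L)),
    seed = derive_seed(config$seed, 9L))
  cmp_path <- file.path(out_dir, "comparison.csv")
  write_comparison(comparison, cmp_path)
  outputs <- c(outputs, cmp_path, sub("\\.csv$", "_folds.csv", cmp_path),
               plan_path)

  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  outputs <- c(outputs, cfg_path)

  manifest <- list(
    package_version =
      as.character(utils::packageVersion("fnacmet")),
    seed = config$seed,
    stage_seeds = list(simulate = derive_seed(config$seed, 1L),
                       select = derive_seed(config$seed, 6L),
                       splits = derive_seed(config$seed, 7L),
                       compare_sae = derive_seed(config$seed, 8L),
                       compare = derive_seed(config$seed, 9L)),
    config_hash = unname(tools::md5sum(cfg_path)),
    stage_counts = stage_counts,
    outputs = lapply(sort(outputs), function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  say("pipeline complete: %d ions after filtering, signature of %d",
      stage_counts$post_filter_features, stage_counts$signature_size)
  invisible(structure(c(manifest, list(
    signature = sig, comparison = comparison, report = cascade$report,
    cohort = cohort, path = man_path)), class = "run_manifest"))
}

#' Command-line interface
#'
#' Thin shell over the package functions, used by the
#' `inst/scripts/fnacmet` launcher. Subcommands: `simulate`, `run`,
#' `align`, `annotate`, `filter`, `select`, `compare`. Returns 0 on
#' success, 2 on usage or validation errors, 1 on runtime errors.
#'
#' @param argv Character vector of arguments (subcommand first).
#' @return Integer exit code.
#' @export
cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: fnacmet <subcommand> [--config FILE] [--out PATH] [--seed N]",
    "  simulate  --out DIR [--config FILE]      write a synthetic cohort",
    "  run       --out DIR [--config FILE]      full pipeline",
    "  align     --metadata FILE --out CSV      align peak lists",
    "  annotate  --table CSV --compounds TSV --out CSV",
    "  filter    --table CSV --compounds TSV --out CSV [--config FILE]",
    "  select    --table CSV --out CSV [--config FILE]",
    "  compare   --table CSV --signature CSV --out CSV [--config FILE]",
    sep = "\n")
  opt <- list()
  if (length(argv) >= 2) {
    flags <- argv[-1]
    keys <- grep("^--", flags)
    for (i in keys) {
      if (i + 1 > length(flags) || grepl("^--", flags[i + 1])) {
        message("missing value for ", flags[i]); return(2L)
      }
      opt[[sub("^--", "", flags[i])]] <- flags[i + 1]
    }
  }
  sub <- if (length(argv)) argv[1] else ""
  run <- function(expr) {
    tryCatch({ expr; 0L },
             fnacmet_error = function(e) { message(conditionMessage(e)); 2L },
             error = function(e) { message(conditionMessage(e)); 1L })
  }
  config <- tryCatch(read_config(opt$config),
                     error = function(e) { message(conditionMessage(e)); NULL })
  if (is.null(config)) return(2L)
  if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)
  need <- function(...) {
    miss <- setdiff(c(...), names(opt))
    if (length(miss)) {
      message("missing required option(s): --",
              paste(miss, collapse = " --"))
      TRUE
    } else FALSE
  }
  switch(sub,
    simulate = {
      if (need("out")) return(2L)
      run(write_cohort(generate_cohort(synthetic_spec_from_config(config)),
                       opt$out))
    },
    run = {
      if (need("out")) return(2L)
      run(run_pipeline(config, out_dir = opt$out))
    },
    align = {
      if (need("metadata", "out")) return(2L)
      run({
        pls <- read_cohort_peaklists(opt$metadata)
        modes <- vapply(pls, `[[`, character(1), "mode")
        tabs <- lapply(unique(modes), function(m)
          join_align(pls[modes == m], config$align$mz_tol_ppm,
                     config$align$rt_tol_min))
        merged <- Reduce(merge_modes, tabs)
        write_feature_table(merged, opt$out)
      })
    },
    annotate = {
      if (need("table", "compounds", "out")) return(2L)
      run({
        tab <- read_feature_table(opt$table)
        ann <- annotate(tab, read_compound_table(opt$compounds),
                        config$annotation$tol_ppm)
        utils::write.csv(ann, opt$out, row.names = FALSE)
      })
    },
    filter = {
      if (need("table", "compounds", "out")) return(2L)
      run({
        tab <- read_feature_table(opt$table)
        ann <- annotate(tab, read_compound_table(opt$compounds),
                        config$annotation$tol_ppm)
        fc <- filter_config(config$filters$min_mean_intensity,
                            config$filters$min_blank_ratio,
                            config$filters$require_adduct_annotation,
                            config$filters$require_evidence_flag)
        res <- apply_cascade(tab, ann, fc)
        write_feature_table(res$table, opt$out)
        write_filter_report(res$report,
                            sub("\\.csv$", "_report.json", opt$out))
      })
    },
    select = {
      if (need("table", "out")) return(2L)
      run({
        tab <- read_feature_table(opt$table)
        norm <- normalize_intensities(tab)
        sig <- topdown_select(model_matrix_from_norm(norm),
                              norm$class_labels, k = config$select$k,
                              drop_fraction = config$select$drop_fraction,
                              config = sae_config_from_config(config),
                              table = tab)
        write_signature(sig, opt$out)
      })
    },
    compare = {
      if (need("table", "signature", "out")) return(2L)
      run({
        tab <- read_feature_table(opt$table)
        sig <- utils::read.csv(opt$signature, stringsAsFactors = FALSE)
        norm <- normalize_intensities(tab)
        X <- model_matrix_from_norm(norm)[, sig$feature_id, drop = FALSE]
        plan <- make_splits(norm$class_labels,
                            config$evaluation$n_repeats,
                            config$evaluation$test_fraction,
                            seed = derive_seed(config$seed, 7L))
        cmp <- compare_models(
          X, norm$class_labels, plan,
          registry = model_registry(sae_cfg =
                                      sae_config_from_config(config, 8L)),
          seed = derive_seed(config$seed, 9L))
        write_comparison(cmp, opt$out)
      })
    },
    {
      message(usage)
      2L
    })
}
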