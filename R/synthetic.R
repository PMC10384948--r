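#' Synthetic LC-MS cohort generator
#'
#' Generates a full study's worth of inputs — per-run peak lists for
#' benign/malignant samples, extraction blanks and pooled QCs in both ion
#' modes, a compound table, and the assembled ground-truth feature table —
#' with planted structure matching the statistical assumptions of the
#' analysis: log-normal intensities, a subset of informative ions with
#' fixed benign/malignant mean-intensity ratios, decoy ions constructed to
#' fail the intensity or blank-ratio filters, and a subset of ions whose
#' m/z values match compound-table adducts. Every feature's fate through
#' the ion-selection cascade is recorded at generation time, so filter
#' bookkeeping can be checked exactly.
#'
#' @name synthetic-data
NULL

# Benign/malignant mean-intensity ratios of the default 15 informative
# ions, spanning |log2 ratio| ~ 0.55 to 2.8, and their ion modes.
DEFAULT_BM_RATIOS <- c(7.002, 4.831, 3.067, 3.125, 0.554, 0.565, 0.573,
                       0.602, 0.590, 0.686, 0.612, 0.682, 0.634, 1.731,
                       5.156)
DEFAULT_INFORMATIVE_MODES <- c("negative", rep("positive", 12), "negative",
                               "positive")

#' Cohort specification
#'
#' Defaults mirror the study design the pipeline targets: 56 benign and
#' 22 malignant samples, 6 blanks and 3 pooled QCs, 5081 positive- and
#' 2609 negative-mode ions of which 15 are informative with the default
#' benign/malignant ratio vector.
#'
#' @param n_benign,n_malignant,n_blanks,n_qc Run counts.
#' @param n_features_pos,n_features_neg Ions per mode.
#' @param n_informative Number of informative (class-separating) ions.
#' @param bm_ratios Benign/malignant mean-intensity ratio per informative
#'   ion.
#' @param informative_modes Ion mode per informative ion (recycled).
#' @param base_log10_mean,base_log10_sd Log10 location and spread of
#'   feature base intensities.
#' @param bio_cv Within-class biological coefficient of variation
#'   (multiplicative, default 0.35).
#' @param blank_contamination_fraction Fraction of non-informative ions
#'   present in blanks strongly enough to fail the 50x blank-ratio rule.
#' @param below_intensity_fraction Fraction of non-informative ions
#'   constructed below the 1e4 mean-intensity floor.
#' @param annotatable_fraction Fraction of ions whose m/z matches a
#'   compound-table adduct within tolerance.
#' @param n_extra_compounds Compound-table entries matching no ion.
#' @param mz_jitter_ppm,rt_jitter_min Per-run measurement jitter bounds.
#' @param rt_range Retention-time support in minutes (default 1-24, the
#'   usable span of a 25-min gradient).
#' @param seed Generator seed; every output is a pure function of the
#'   spec including this seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_benign = 56, n_malignant = 22, n_blanks = 6,
                        n_qc = 3, n_features_pos = 5081,
                        n_features_neg = 2609, n_informative = 15,
                        bm_ratios = DEFAULT_BM_RATIOS,
                        informative_modes = DEFAULT_INFORMATIVE_MODES,
                        base_log10_mean = 4.8, base_log10_sd = 0.6,
                        bio_cv = 0.35,
                        blank_contamination_fraction = 0.25,
                        below_intensity_fraction = 0.30,
                        annotatable_fraction = 0.45,
                        n_extra_compounds = 50,
                        mz_jitter_ppm = 3, rt_jitter_min = 0.2,
                        rt_range = c(1, 24), seed = 1) {
  fr <- c(blank_contamination_fraction, below_intensity_fraction,
          annotatable_fraction)
  if (any(fr < 0) || any(fr > 1))
    abort_validation("fractions must lie in [0, 1]")
  if (n_informative > length(bm_ratios))
    bm_ratios <- rep_len(bm_ratios, n_informative)
  bm_ratios <- bm_ratios[seq_len(n_informative)]
  informative_modes <- rep_len(informative_modes, n_informative)
  if (any(bm_ratios <= 0))
    abort_validation("bm_ratios must be positive")
  if (n_benign < 2 || n_malignant < 2 || n_blanks < 1)
    abort_validation("need >= 2 samples per class and >= 1 blank")
  structure(list(n_benign = n_benign, n_malignant = n_malignant,
                 n_blanks = n_blanks, n_qc = n_qc,
                 n_features_pos = n_features_pos,
                 n_features_neg = n_features_neg,
                 n_informative = n_informative, bm_ratios = bm_ratios,
                 informative_modes = informative_modes,
                 base_log10_mean = base_log10_mean,
                 base_log10_sd = base_log10_sd, bio_cv = bio_cv,
                 blank_contamination_fraction = blank_contamination_fraction,
                 below_intensity_fraction = below_intensity_fraction,
                 annotatable_fraction = annotatable_fraction,
                 n_extra_compounds = n_extra_compounds,
                 mz_jitter_ppm = mz_jitter_ppm,
                 rt_jitter_min = rt_jitter_min, rt_range = rt_range,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Named compounds planted for fixture realism (formula-derived masses).
SPECIAL_COMPOUNDS <- data.frame(
  compound_id = c("SYN_C11H3O13P3", "HMDB0038361", "HMDB0003840"),
  name = c("", "(-)-Epigallocatechin", "Phosphoroselenoic acid"),
  formula = c("C11H3O13P3", "C15H14O7", "H3O3PSe"),
  mode = c("negative", "positive", "positive"),
  stringsAsFactors = FALSE)

#' Generate a synthetic compound table
#'
#' `n` records with monoisotopic masses drawn uniformly from
#' `mass_range`, mutually separated by at least `min_sep_ppm` so planted
#' identities re-annotate uniquely, plus a handful of named records with
#' formula-derived masses.
#'
#' @param n Number of random records (>= 1).
#' @param mass_range Mass support in Da (default 80-999).
#' @param seed RNG seed.
#' @param min_sep_ppm Minimum mutual spacing (default 40 ppm).
#' @param include_named Include the named formula records (default TRUE).
#' @return Compound data frame.
#' @export
generate_compound_db <- function(n, mass_range = c(80, 999), seed = 1,
                                 min_sep_ppm = 40, include_named = TRUE) {
  if (n < 1) abort_validation("`n` must be at least 1")
  named <- if (include_named) {
    data.frame(compound_id = SPECIAL_COMPOUNDS$compound_id,
               name = SPECIAL_COMPOUNDS$name,
               formula = SPECIAL_COMPOUNDS$formula,
               monoisotopic_mass = vapply(SPECIAL_COMPOUNDS$formula,
                                          monoisotopic_mass, numeric(1)),
               stringsAsFactors = FALSE)
  } else NULL
  masses <- with_seed(seed, {
    fixed <- named$monoisotopic_mass %||% numeric(0)
    m <- stats::runif(n, mass_range[1], mass_range[2])
    bad <- integer(0)
    for (iter in 1:200) {
      all_m <- c(fixed, m)
      o <- order(all_m)
      gap_ok <- c(TRUE, diff(all_m[o]) / all_m[o][-1] * 1e6 >= min_sep_ppm)
      bad <- o[!gap_ok]
      bad <- bad[bad > length(fixed)] - length(fixed)
      if (!length(bad)) break
      m[bad] <- stats::runif(length(bad), mass_range[1], mass_range[2])
    }
    if (length(bad))
      abort_validation("cannot satisfy mass spacing; widen mass_range")
    m
  })
  rand <- data.frame(
    compound_id = sprintf("SYNDB%06d", seq_len(n)),
    name = sprintf("synthetic_compound_%04d", seq_len(n)),
    formula = "", monoisotopic_mass = masses,
    stringsAsFactors = FALSE)
  rbind(named, rand)
}

# per-mode feature plan: strata and annotatable flags, count-exact
plan_mode_features <- function(n, n_inf, spec) {
  stratum <- rep("clean", n)
  stratum[seq_len(n_inf)] <- "informative"
  rest <- setdiff(seq_len(n), seq_len(n_inf))
  n_below <- round(spec$below_intensity_fraction * length(rest))
  n_blank <- round(spec$blank_contamination_fraction * length(rest))
  shuffled <- sample(rest)
  stratum[shuffled[seq_len(n_below)]] <- "below_intensity"
  stratum[shuffled[n_below + seq_len(n_blank)]] <- "blank_contaminated"
  annot <- rep(FALSE, n)
  annot[seq_len(n_inf)] <- TRUE
  for (s in c("below_intensity", "blank_contaminated", "clean")) {
    idx <- which(stratum == s)
    k <- round(spec$annotatable_fraction * length(idx))
    if (k > 0) annot[sample(idx, k)] <- TRUE
  }
  list(stratum = stratum, annotatable = annot)
}

rnorm_trunc_min <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  for (iter in 1:100) {
    bad <- which(x < lower)
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
  pmax(x, lower)
}

#' Generate a full synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @param make_peak_lists Also materialise the per-run jittered peak
#'   lists (default TRUE; disable when only the assembled table is
#'   needed, e.g. for large-sample simulations).
#' @return A `synthetic_cohort` list with elements `peak_lists` (all runs,
#'   both modes), `compounds`, `truth_table` (the assembled
#'   [feature_table] whose intensities are the per-run generated values),
#'   `ground_truth` (per-feature fates) and `expected_survivors`.
#' @export
generate_cohort <- function(spec = cohort_spec(), make_peak_lists = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  sigma <- sqrt(log(1 + spec$bio_cv^2)) / log(10)
  run_meta <- data.frame(
    run_id = c(sprintf("B%03d", seq_len(spec$n_benign)),
               sprintf("M%03d", seq_len(spec$n_malignant)),
               sprintf("BLK%02d", seq_len(spec$n_blanks)),
               if (spec$n_qc) sprintf("QC%02d", seq_len(spec$n_qc))),
    role = c(rep("sample", spec$n_benign + spec$n_malignant),
             rep("blank", spec$n_blanks), rep("qc", spec$n_qc)),
    class_label = c(rep("benign", spec$n_benign),
                    rep("malignant", spec$n_malignant),
                    rep("none", spec$n_blanks + spec$n_qc)),
    stringsAsFactors = FALSE)
  is_ben <- run_meta$class_label == "benign"
  is_mal <- run_meta$class_label == "malignant"
  is_blk <- run_meta$role == "blank"
  is_qc <- run_meta$role == "qc"

  with_seed(spec$seed, {
    n_annot_total <- 0L
    mode_info <- list()
    for (mode in c("positive", "negative")) {
      n <- if (mode == "positive") spec$n_features_pos else
        spec$n_features_neg
      inf_idx <- which(spec$informative_modes == mode)
      plan <- plan_mode_features(n, length(inf_idx), spec)
      mode_info[[mode]] <- list(n = n, inf_idx = inf_idx, plan = plan)
      n_annot_total <- n_annot_total + sum(plan$annotatable)
    }
    compounds <- generate_compound_db(
      max(n_annot_total, 1L) + spec$n_extra_compounds,
      seed = derive_seed(spec$seed, 97L))
    # named records are reserved for informative ions of matching mode;
    # random records back the remaining annotatable ions
    rand_ids <- compounds$compound_id[nzchar(compounds$formula) == FALSE]
    rand_pool <- sample(rand_ids)
    pool_ptr <- 0L

    tables <- list()
    gt <- list()
    for (mode in c("positive", "negative")) {
      mi <- mode_info[[mode]]
      n <- mi$n
      plan <- mi$plan
      n_inf <- length(mi$inf_idx)
      ratios <- spec$bm_ratios[mi$inf_idx]

      # compound assignment for annotatable features
      comp_id <- rep(NA_character_, n)
      specials <- SPECIAL_COMPOUNDS$compound_id[
        SPECIAL_COMPOUNDS$mode == mode]
      if (n_inf > 0) {
        take <- seq_len(min(length(specials), n_inf))
        comp_id[take] <- specials[take]
      }
      need <- which(plan$annotatable & is.na(comp_id))
      comp_id[need] <- rand_pool[pool_ptr + seq_along(need)]
      pool_ptr <- pool_ptr + length(need)

      # true m/z: adduct of the assigned compound, or a decoy m/z kept
      # >= 25 ppm away from every same-mode adduct in the table
      cmass <- compounds$monoisotopic_mass[
        match(comp_id, compounds$compound_id)]
      db_mz <- sort(mz_from_neutral_mass(compounds$monoisotopic_mass, mode))
      mz <- ifelse(is.na(cmass), NA_real_,
                   mz_from_neutral_mass(cmass, mode))
      todo <- which(is.na(mz))
      draw <- stats::runif(length(todo), 81, 1000)
      for (iter in 1:200) {
        near <- findInterval(draw, db_mz)
        d_lo <- abs(draw - db_mz[pmax(near, 1L)]) / draw * 1e6
        d_hi <- abs(draw - db_mz[pmin(near + 1L, length(db_mz))]) /
          draw * 1e6
        bad <- which(pmin(d_lo, d_hi) < 25)
        if (!length(bad)) break
        draw[bad] <- stats::runif(length(bad), 81, 1000)
      }
      mz[todo] <- draw
      rt <- stats::runif(n, spec$rt_range[1], spec$rt_range[2])
      # alignment separability: same-m/z features must differ in RT
      o <- order(mz)
      for (iter in 1:200) {
        conflict <- integer(0)
        om <- mz[o]; ort <- rt[o]
        j <- 1L
        for (i in seq_len(n - 1L)) {
          k <- i + 1L
          while (k <= n && (om[k] - om[i]) / om[i] * 1e6 <= 30) {
            if (abs(ort[k] - ort[i]) < 1.5) conflict <- c(conflict, o[k])
            k <- k + 1L
          }
        }
        conflict <- unique(conflict)
        if (!length(conflict)) break
        rt[conflict] <- stats::runif(length(conflict), spec$rt_range[1],
                                     spec$rt_range[2])
        ort <- rt[o]
      }

      # base log10 intensity by stratum
      mu <- numeric(n)
      pass <- plan$stratum %in% c("clean", "blank_contaminated")
      mu[pass] <- rnorm_trunc_min(sum(pass), spec$base_log10_mean,
                                  spec$base_log10_sd, log10(3e4))
      low <- plan$stratum == "below_intensity"
      mu[low] <- stats::runif(sum(low), 2.5, 3.6)
      infi <- plan$stratum == "informative"
      mu[infi] <- rnorm_trunc_min(sum(infi), spec$base_log10_mean,
                                  spec$base_log10_sd, 4.7)

      delta <- numeric(n)
      delta[seq_len(n_inf)] <- log10(ratios) / 2

      n_runs <- nrow(run_meta)
      intens <- matrix(0, n, n_runs)
      mu_b <- mu + delta
      mu_m <- mu - delta
      nb <- sum(is_ben); nm <- sum(is_mal)
      intens[, is_ben] <- 10^(mu_b +
        matrix(stats::rnorm(n * nb, 0, sigma), n, nb))
      intens[, is_mal] <- 10^(mu_m +
        matrix(stats::rnorm(n * nm, 0, sigma), n, nm))
      if (any(is_qc)) {
        pooled <- rowMeans(intens[, is_ben, drop = FALSE])
        nq <- sum(is_qc)
        intens[, is_qc] <- pooled *
          10^matrix(stats::rnorm(n * nq, 0, 0.02), n, nq)
      }
      smean <- rowMeans(intens[, is_ben | is_mal, drop = FALSE])
      blk <- plan$stratum == "blank_contaminated"
      if (any(blk) && any(is_blk)) {
        r_target <- stats::runif(sum(blk), 2, 40)
        nbl <- sum(is_blk)
        intens[blk, is_blk] <- (smean[blk] / r_target) *
          10^matrix(stats::rnorm(sum(blk) * nbl, 0, 0.05), sum(blk), nbl)
        bmean <- rowMeans(intens[blk, is_blk, drop = FALSE])
        realized <- smean[blk] / bmean
        fix <- which(realized >= 45)
        if (length(fix)) {
          rows <- which(blk)[fix]
          intens[rows, is_blk] <- intens[rows, is_blk, drop = FALSE] *
            (realized[fix] / 44)
        }
      }

      prefix <- if (mode == "positive") "pos" else "neg"
      fid <- sprintf("%s_T%05d", prefix, seq_len(n))
      features <- data.frame(feature_id = fid, mode = mode, mz = mz,
                             rt = rt, evidence_flag = TRUE,
                             stringsAsFactors = FALSE)
      tables[[mode]] <- feature_table(features, run_meta, intens)
      gt[[mode]] <- data.frame(
        feature_id = fid, mode = mode, mz = mz, rt = rt,
        informative = plan$stratum == "informative",
        bm_ratio_true = c(ratios, rep(1, n - n_inf)),
        stratum = plan$stratum,
        annotatable = plan$annotatable,
        survives_intensity = plan$stratum != "below_intensity",
        survives_blank = plan$stratum != "blank_contaminated",
        compound_id = comp_id,
        stringsAsFactors = FALSE)
    }

    ground_truth <- rbind(gt$positive, gt$negative)
    ground_truth$survives_cascade <- ground_truth$annotatable &
      ground_truth$survives_intensity & ground_truth$survives_blank
    truth_table <- merge_modes(tables$positive, tables$negative)

    peak_lists <- list()
    if (make_peak_lists) for (mode in c("positive", "negative")) {
      tab <- tables[[mode]]
      for (j in seq_len(nrow(run_meta))) {
        v <- tab$intensities[, j]
        present <- which(v > 0)
        npk <- length(present)
        pk <- data.frame(
          mz = tab$features$mz[present] *
            (1 + stats::runif(npk, -spec$mz_jitter_ppm,
                              spec$mz_jitter_ppm) * 1e-6),
          rt = pmax(tab$features$rt[present] +
                      stats::runif(npk, -spec$rt_jitter_min,
                                   spec$rt_jitter_min), 0),
          intensity = v[present])
        peak_lists[[paste(mode, run_meta$run_id[j], sep = ":")]] <-
          peak_list(run_id = run_meta$run_id[j],
                    role = run_meta$role[j], mode = mode,
                    class_label = run_meta$class_label[j], peaks = pk)
      }
    }

    structure(list(spec = spec, peak_lists = peak_lists,
                   compounds = compounds, truth_table = truth_table,
                   ground_truth = ground_truth,
                   expected_survivors = sum(ground_truth$survives_cascade),
                   informative_ids = ground_truth$feature_id[
                     ground_truth$informative]),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d features x %d runs; %d informative, %d expected cascade survivors\n",
    nrow(x$truth_table$features), nrow(x$truth_table$samples),
    length(x$informative_ids), x$expected_survivors))
  invisible(x)
}

#' Seed-locked miniature cohort used by tests and documentation
#'
#' A deterministic scaled-down cohort: the full 56 benign + 22 malignant
#' sample design with 6 blanks and 3 QCs, but 500 positive- and 200
#' negative-mode ions so that every stage runs in seconds. The 15
#' informative ions carry the default benign/malignant ratio vector.
#'
#' @return A `synthetic_cohort`.
#' @export
fixture_cohort <- function() {
  generate_cohort(cohort_spec(n_features_pos = 500, n_features_neg = 200,
                              n_extra_compounds = 40, seed = 782L))
}

#' Match aligned features back to generator ground truth
#'
#' Links each aligned feature to the ground-truth feature of the same
#' mode nearest in (m/z, RT), within the alignment tolerances.
#'
#' @param table An aligned [feature_table].
#' @param ground_truth The `ground_truth` data frame of a cohort.
#' @param mz_tol_ppm,rt_tol_min Matching tolerances.
#' @return Data frame with `feature_id` and matched `truth_id` (NA when
#'   unmatched).
#' @export
match_ground_truth <- function(table, ground_truth, mz_tol_ppm = 10,
                               rt_tol_min = 1.0) {
  stopifnot(inherits(table, "feature_table"))
  out <- data.frame(feature_id = table$features$feature_id,
                    truth_id = NA_character_, stringsAsFactors = FALSE)
  for (mode in unique(table$features$mode)) {
    fi <- which(table$features$mode == mode)
    gi <- which(ground_truth$mode == mode)
    if (!length(fi) || !length(gi)) next
    for (i in fi) {
      dppm <- abs(table$features$mz[i] - ground_truth$mz[gi]) /
        ground_truth$mz[gi] * 1e6
      drt <- abs(table$features$rt[i] - ground_truth$rt[gi])
      ok <- which(dppm <= mz_tol_ppm & drt <= rt_tol_min)
      if (length(ok)) {
        best <- ok[which.min(dppm[ok] / mz_tol_ppm + drt[ok] / rt_tol_min)]
        out$truth_id[i] <- ground_truth$feature_id[gi[best]]
      }
    }
  }
  out
}
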