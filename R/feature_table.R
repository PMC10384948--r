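#' Aligned feature tables
#'
#' A `feature_table` is the ions-by-samples intensity matrix produced by
#' cross-run alignment: one row per aligned feature (consensus m/z and
#' retention time within one ion mode), one column per run. A zero entry
#' means the feature was not detected in that run.
#'
#' @param features Data frame with columns `feature_id`, `mode`, `mz`,
#'   `rt`, `evidence_flag`.
#' @param samples Data frame with columns `run_id`, `role`, `class_label`.
#' @param intensities Numeric matrix, `nrow(features)` x `nrow(samples)`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, samples, intensities) {
  features <- as.data.frame(features)
  samples <- as.data.frame(samples)
  if (is.null(features$evidence_flag)) features$evidence_flag <- TRUE
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(features) ||
      ncol(intensities) != nrow(samples))
    abort_validation(
      "intensity matrix is %d x %d but there are %d features and %d samples",
      nrow(intensities), ncol(intensities), nrow(features), nrow(samples))
  if (nrow(intensities) && any(intensities < 0))
    abort_validation("intensity matrix must be non-negative")
  if (anyDuplicated(features$feature_id))
    abort_validation("duplicated feature_id in feature table")
  if (anyDuplicated(samples$run_id))
    abort_validation("duplicated run_id in feature table")
  rownames(intensities) <- features$feature_id
  colnames(intensities) <- samples$run_id
  structure(list(features = features, samples = samples,
                 intensities = intensities),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$samples$role)
  cat(sprintf("<feature_table> %d features x %d runs (%s)\n",
              nrow(x$features), nrow(x$samples),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Keep a subset of features, preserving sample order
#' @param table A [feature_table].
#' @param keep Logical or indexing vector over features.
#' @return The subset [feature_table].
#' @export
subset_features <- function(table, keep) {
  stopifnot(inherits(table, "feature_table"))
  feature_table(table$features[keep, , drop = FALSE],
                table$samples,
                table$intensities[keep, , drop = FALSE])
}

sample_columns <- function(table, role) which(table$samples$role == role)

#' Align same-mode peak lists into a feature table
#'
#' Greedy agglomerative alignment in the style of a join aligner: runs are
#' processed in lexicographic `run_id` order; each peak either joins the
#' existing feature minimising a combined normalised distance
#' (`|ppm|/mz_tol_ppm + |dRT|/rt_tol_min`) when both tolerances hold, or
#' founds a new feature. Within a run each feature accepts at most one
#' peak; on conflict the better-scoring peak wins and the loser founds a
#' new feature. Consensus m/z and RT are intensity-weighted means of the
#' member peaks, updated after each run is joined.
#'
#' @param peak_lists List of [peak_list] objects, all in the same ion mode.
#' @param mz_tol_ppm m/z tolerance in parts per million (default 10).
#' @param rt_tol_min Retention-time tolerance in minutes (default 1.0).
#' @return A [feature_table] with one column per run.
#' @export
join_align <- function(peak_lists, mz_tol_ppm = 10, rt_tol_min = 1.0) {
  if (!length(peak_lists))
    abort_validation("`peak_lists` must contain at least one run")
  if (!all(vapply(peak_lists, inherits, logical(1), "peak_list")))
    abort_validation("`peak_lists` must be a list of peak_list objects")
  modes <- unique(vapply(peak_lists, `[[`, character(1), "mode"))
  if (length(modes) != 1L)
    abort_validation("mixed ion modes in join_align: %s",
                     paste(modes, collapse = ", "))
  assert_scalar_number(mz_tol_ppm, "mz_tol_ppm", positive = TRUE)
  assert_scalar_number(rt_tol_min, "rt_tol_min", positive = TRUE)

  ids <- vapply(peak_lists, `[[`, character(1), "run_id")
  if (anyDuplicated(ids)) abort_validation("duplicated run_id among runs")
  ord <- order(ids)
  peak_lists <- peak_lists[ord]
  ids <- ids[ord]
  n_runs <- length(peak_lists)

  # growing consensus state
  cons_mz <- numeric(0)   # intensity-weighted consensus m/z
  cons_rt <- numeric(0)
  w_mz <- numeric(0)      # sum(w * mz), sum(w * rt), sum(w)
  w_rt <- numeric(0)
  w_sum <- numeric(0)
  cells <- vector("list", n_runs)  # per run: data.frame(feature, intensity)

  for (r in seq_len(n_runs)) {
    pk <- peak_lists[[r]]$peaks
    np <- nrow(pk)
    assign_to <- integer(np)           # 0 = found new feature
    if (np && length(cons_mz)) {
      dmz_ppm <- abs(outer(pk$mz, cons_mz, function(a, b) (a - b) / b * 1e6))
      drt <- abs(outer(pk$rt, cons_rt, `-`))
      score <- dmz_ppm / mz_tol_ppm + drt / rt_tol_min
      score[dmz_ppm > mz_tol_ppm | drt > rt_tol_min] <- Inf
      best <- max.col(-score, ties.method = "first")
      best_score <- score[cbind(seq_len(np), best)]
      cand <- which(is.finite(best_score))
      # resolve conflicts: each feature keeps only its best-scoring peak
      if (length(cand)) {
        keep <- cand[order(best_score[cand], cand)]
        taken <- logical(length(cons_mz))
        for (i in keep) {
          f <- best[i]
          if (!taken[f]) {
            taken[f] <- TRUE
            assign_to[i] <- f
          }
        }
      }
    }
    # losers and unmatched peaks found new features, in row order
    new_idx <- which(assign_to == 0L)
    if (length(new_idx)) {
      base <- length(cons_mz)
      assign_to[new_idx] <- base + seq_along(new_idx)
      cons_mz <- c(cons_mz, pk$mz[new_idx])
      cons_rt <- c(cons_rt, pk$rt[new_idx])
      w_new <- pmax(pk$intensity[new_idx], 1e-12)
      w_mz <- c(w_mz, w_new * pk$mz[new_idx])
      w_rt <- c(w_rt, w_new * pk$rt[new_idx])
      w_sum <- c(w_sum, w_new)
    }
    # fold matched peaks into the consensus (intensity-weighted)
    matched <- which(assign_to > 0L & !seq_len(np) %in% new_idx)
    if (length(matched)) {
      f <- assign_to[matched]
      w <- pmax(pk$intensity[matched], 1e-12)
      w_mz[f] <- w_mz[f] + w * pk$mz[matched]
      w_rt[f] <- w_rt[f] + w * pk$rt[matched]
      w_sum[f] <- w_sum[f] + w
      cons_mz[f] <- w_mz[f] / w_sum[f]
      cons_rt[f] <- w_rt[f] / w_sum[f]
    }
    cells[[r]] <- data.frame(feature = assign_to,
                             intensity = pk$intensity)
  }

  n_feat <- length(cons_mz)
  intens <- matrix(0, nrow = n_feat, ncol = n_runs)
  for (r in seq_len(n_runs)) {
    cl <- cells[[r]]
    if (nrow(cl)) intens[cl$feature, r] <- cl$intensity
  }
  mode <- modes
  prefix <- if (mode == "positive") "pos" else "neg"
  features <- data.frame(
    feature_id = sprintf("%s_F%05d", prefix, seq_len(n_feat)),
    mode = mode, mz = cons_mz, rt = cons_rt, evidence_flag = TRUE,
    stringsAsFactors = FALSE)
  samples <- data.frame(
    run_id = ids,
    role = vapply(peak_lists, `[[`, character(1), "role"),
    class_label = vapply(peak_lists, `[[`, character(1), "class_label"),
    stringsAsFactors = FALSE)
  feature_table(features, samples, intens)
}

#' Merge positive- and negative-mode feature tables
#'
#' Row-wise concatenation of two same-cohort tables into the single
#' compiled database used by all downstream statistics. Sample order
#' follows the positive-mode table.
#'
#' @param pos,neg [feature_table] objects sharing the same set of run ids.
#' @return The combined [feature_table].
#' @export
merge_modes <- function(pos, neg) {
  stopifnot(inherits(pos, "feature_table"), inherits(neg, "feature_table"))
  if (nrow(neg$features) == 0L) return(pos)
  only_pos <- setdiff(pos$samples$run_id, neg$samples$run_id)
  only_neg <- setdiff(neg$samples$run_id, pos$samples$run_id)
  if (length(only_pos) || length(only_neg))
    abort_validation(
      "sample sets differ between modes (only in pos: %s; only in neg: %s)",
      paste(only_pos, collapse = ",") , paste(only_neg, collapse = ","))
  idx <- match(pos$samples$run_id, neg$samples$run_id)
  feature_table(rbind(pos$features, neg$features),
                pos$samples,
                rbind(pos$intensities, neg$intensities[, idx, drop = FALSE]))
}

#' Write a feature table as a wide CSV plus JSON sample sidecar
#'
#' The CSV starts with columns `feature_id`, `mode`, `mz`, `rt_min`,
#' `evidence_flag` followed by one intensity column per run. Sample
#' metadata (role and class label per run) go to `<path>.samples.json`.
#'
#' @param table A [feature_table].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  wide <- cbind(
    data.frame(feature_id = table$features$feature_id,
               mode = table$features$mode,
               mz = table$features$mz,
               rt_min = table$features$rt,
               evidence_flag = table$features$evidence_flag),
    as.data.frame(table$intensities))
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(table$samples, paste0(path, ".samples.json"),
                       dataframe = "rows", auto_unbox = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path (its `.samples.json` sidecar must sit next to it).
#' @return A [feature_table].
#' @export
read_feature_table <- function(path) {
  wide <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("feature_id", "mode", "mz", "rt_min", "evidence_flag")
  if (!all(meta_cols %in% names(wide)))
    abort_format("feature-table CSV '%s' lacks metadata columns", path)
  samples <- jsonlite::read_json(paste0(path, ".samples.json"),
                                 simplifyVector = TRUE)
  features <- data.frame(feature_id = wide$feature_id, mode = wide$mode,
                         mz = wide$mz, rt = wide$rt_min,
                         evidence_flag = as.logical(wide$evidence_flag))
  feature_table(features, samples,
                as.matrix(wide[, samples$run_id, drop = FALSE]))
}
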