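#' Intensity normalisation
#'
#' Raw peak intensities are log-normally distributed and span orders of
#' magnitude, so all modelling works on a per-feature standardised log10
#' scale: zeros (non-detections) are imputed with half the smallest
#' positive training intensity of that feature, intensities are log10
#' transformed, then centred and scaled using training-partition
#' statistics only. Transform parameters are stored so that held-out
#' samples can be mapped with the training parameters, never their own.
#'
#' @param table A [feature_table].
#' @param training_ids Run ids forming the training partition; defaults to
#'   all sample runs. Statistics are computed on these columns only.
#' @param roles Which roles to include as columns of the output matrix
#'   (default `"sample"`).
#' @return A `normalized_matrix`: list with `values` (features x samples),
#'   `feature_means`, `feature_sds`, `log_offset` (per-feature imputation
#'   value on the raw scale), `training_ids`.
#' @export
normalize_intensities <- function(table, training_ids = NULL,
                                  roles = "sample") {
  stopifnot(inherits(table, "feature_table"))
  keep <- table$samples$role %in% roles
  mat <- table$intensities[, keep, drop = FALSE]
  samples <- table$samples[keep, , drop = FALSE]
  if (is.null(training_ids)) training_ids <- samples$run_id
  tr <- samples$run_id %in% training_ids
  if (!any(tr)) abort_validation("no training samples found")
  train <- mat[, tr, drop = FALSE]

  all_zero <- rowSums(train > 0) == 0
  if (any(all_zero))
    abort_validation(
      "feature '%s' has no positive intensity in the training partition",
      table$features$feature_id[which(all_zero)[1]])
  log_offset <- apply(train, 1L, function(v) min(v[v > 0]) / 2)

  imputed <- mat
  zero <- imputed == 0
  imputed[zero] <- log_offset[row(imputed)[zero]]
  lg <- log10(imputed)

  lg_train <- lg[, tr, drop = FALSE]
  feature_means <- rowMeans(lg_train)
  feature_sds <- apply(lg_train, 1L, stats::sd)
  feature_sds[!is.finite(feature_sds) | feature_sds < 1e-12] <- 1e-12
  values <- (lg - feature_means) / feature_sds

  structure(list(values = values,
                 samples = samples,
                 class_labels = samples$class_label,
                 feature_ids = table$features$feature_id,
                 feature_means = feature_means,
                 feature_sds = feature_sds,
                 log_offset = log_offset,
                 training_ids = intersect(samples$run_id, training_ids)),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d features x %d samples (%d training)\n",
              nrow(x$values), ncol(x$values), length(x$training_ids)))
  invisible(x)
}

#' Map new raw intensities with stored training parameters
#' @param norm A `normalized_matrix`.
#' @param mat Raw intensity matrix (features x new samples), rows in the
#'   same feature order.
#' @return Standardised log10 matrix.
#' @export
apply_normalization <- function(norm, mat) {
  stopifnot(inherits(norm, "normalized_matrix"))
  mat <- as.matrix(mat)
  if (nrow(mat) != length(norm$feature_means))
    abort_validation("row count does not match the stored parameters")
  zero <- mat == 0
  mat[zero] <- norm$log_offset[row(mat)[zero]]
  (log10(mat) - norm$feature_means) / norm$feature_sds
}

#' Invert the centre/scale step, recovering log10 intensities
#' @param norm A `normalized_matrix`.
#' @return Matrix of log10 imputed intensities.
#' @export
denormalize <- function(norm) {
  stopifnot(inherits(norm, "normalized_matrix"))
  norm$values * norm$feature_sds + norm$feature_means
}

# samples x features orientation used by the modelling code
model_matrix_from_norm <- function(norm) t(norm$values)
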