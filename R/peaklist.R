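#' Per-run LC-MS peak lists
#'
#' A `peak_list` holds the detected peaks of one chromatographic run
#' together with its metadata: the run identifier, its role in the study
#' (biological sample, extraction blank, or pooled quality control), the
#' ionisation mode, and the diagnostic class label for sample runs.
#'
#' @param run_id Character scalar run identifier.
#' @param role One of `"sample"`, `"blank"`, `"qc"`.
#' @param mode Ion mode, `"positive"` or `"negative"`.
#' @param class_label `"benign"`, `"malignant"` or `"none"`. Blank and QC
#'   runs must carry `"none"`.
#' @param peaks Data frame with numeric columns `mz`, `rt`, `intensity`.
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(run_id, role = c("sample", "blank", "qc"),
                      mode = c("positive", "negative"),
                      class_label = c("none", "benign", "malignant"),
                      peaks = data.frame(mz = numeric(), rt = numeric(),
                                         intensity = numeric())) {
  role <- match.arg(role)
  mode <- match.arg(mode)
  class_label <- match.arg(class_label)
  if (!is.character(run_id) || length(run_id) != 1L || !nzchar(run_id))
    abort_validation("`run_id` must be a non-empty string")
  if (role %in% c("blank", "qc") && class_label != "none")
    abort_validation("run '%s': role '%s' requires class_label 'none'",
                     run_id, role)
  if (role == "sample" && class_label == "none")
    abort_validation("run '%s': sample runs need a benign/malignant label",
                     run_id)
  needed <- c("mz", "rt", "intensity")
  if (!all(needed %in% names(peaks)))
    abort_format("`peaks` must have columns mz, rt, intensity")
  peaks <- as.data.frame(peaks)[, needed]
  if (nrow(peaks)) {
    if (any(!is.finite(peaks$mz)) || any(peaks$mz <= 0))
      abort_validation("run '%s': all m/z values must be positive", run_id)
    if (any(peaks$rt < 0))
      abort_validation("run '%s': retention times must be non-negative", run_id)
    if (any(peaks$intensity < 0))
      abort_validation("run '%s': intensities must be non-negative", run_id)
  }
  structure(list(run_id = run_id, role = role, mode = mode,
                 class_label = class_label, peaks = peaks),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> run '%s' (%s, %s mode, label %s): %d peaks\n",
              x$run_id, x$role, x$mode, x$class_label, nrow(x$peaks)))
  invisible(x)
}

#' Read a peak-list CSV
#'
#' The expected format is a UTF-8 CSV with header columns `mz`, `rt_min`
#' and `intensity` ("." decimal separator), one row per detected peak.
#' Row order is preserved.
#'
#' @param path Path to the CSV file.
#' @inheritParams peak_list
#' @return A [peak_list].
#' @export
read_peak_list <- function(path, run_id, role = "sample", mode = "positive",
                           class_label = "none") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("mz", "rt_min", "intensity")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    abort_format("peak-list file '%s' is missing column(s): %s",
                 path, paste(missing_cols, collapse = ", "))
  bad <- which(df$intensity < 0)
  if (length(bad))
    abort_validation("peak-list file '%s': negative intensity at row %d",
                     path, bad[1])
  peak_list(run_id = run_id, role = role, mode = mode,
            class_label = class_label,
            peaks = data.frame(mz = df$mz, rt = df$rt_min,
                               intensity = df$intensity))
}

#' Write a peak list to CSV in the package's interchange format
#' @param pl A [peak_list].
#' @param path Output path.
#' @export
write_peak_list <- function(pl, path) {
  stopifnot(inherits(pl, "peak_list"))
  utils::write.csv(
    data.frame(mz = pl$peaks$mz, rt_min = pl$peaks$rt,
               intensity = pl$peaks$intensity),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
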