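#' Ion-selection cascade
#'
#' The quality-control cascade that reduces the aligned ion set to the
#' analyzable ions: (1) keep only ions with a proton-adduct annotation,
#' (2) keep ions whose mean intensity over biological samples reaches a
#' noise floor, (3) keep ions whose sample/blank mean-intensity ratio
#' shows they are not extraction background, and optionally (4) keep ions
#' carrying the dual-software evidence flag. Each stage is inclusive at
#' its threshold.
#'
#' @name qc-filtering
NULL

#' Filter configuration
#'
#' @param min_mean_intensity Minimum arithmetic mean intensity over sample
#'   runs, zeros (non-detections) included. Default `1e4`. Set to 0 to
#'   skip the stage.
#' @param min_blank_ratio Minimum ratio of mean sample intensity to mean
#'   blank intensity. Default 50. Set to 0 to skip the stage.
#' @param require_adduct_annotation Keep only annotated ions (default TRUE).
#' @param require_evidence_flag Keep only ions whose `evidence_flag` is
#'   TRUE (default FALSE).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_mean_intensity = 1e4, min_blank_ratio = 50,
                          require_adduct_annotation = TRUE,
                          require_evidence_flag = FALSE) {
  if (min_mean_intensity < 0 || min_blank_ratio < 0)
    abort_validation("filter thresholds must be non-negative")
  structure(list(min_mean_intensity = min_mean_intensity,
                 min_blank_ratio = min_blank_ratio,
                 require_adduct_annotation = isTRUE(require_adduct_annotation),
                 require_evidence_flag = isTRUE(require_evidence_flag)),
            class = "filter_config")
}

feature_sample_means <- function(table) {
  sc <- sample_columns(table, "sample")
  if (!length(sc))
    abort_validation("feature table has no sample runs")
  rowMeans(table$intensities[, sc, drop = FALSE])
}

#' Mean-intensity noise filter
#'
#' Retains features whose arithmetic mean intensity over sample runs
#' (zeros included) is at least `threshold`.
#'
#' @param table A [feature_table].
#' @param threshold Intensity floor (inclusive).
#' @return Filtered [feature_table].
#' @export
mean_intensity_filter <- function(table, threshold = 1e4) {
  stopifnot(inherits(table, "feature_table"))
  if (!nrow(table$features)) return(table)
  subset_features(table, feature_sample_means(table) >= threshold)
}

#' Blank-ratio background filter
#'
#' Retains features whose mean intensity over sample runs is at least
#' `ratio` times the mean over blank runs. Features absent from every
#' blank (blank mean 0) are maximally sample-specific and are always
#' retained.
#'
#' @param table A [feature_table]; must contain at least one blank run.
#' @param ratio Required sample/blank ratio (inclusive, default 50).
#' @return Filtered [feature_table].
#' @export
blank_ratio_filter <- function(table, ratio = 50) {
  stopifnot(inherits(table, "feature_table"))
  if (!nrow(table$features)) return(table)
  bc <- sample_columns(table, "blank")
  if (!length(bc))
    abort_validation("feature table has no blank runs")
  smean <- feature_sample_means(table)
  bmean <- rowMeans(table$intensities[, bc, drop = FALSE])
  r <- ifelse(bmean == 0, Inf, smean / bmean)
  subset_features(table, r >= ratio)
}

#' Adduct-annotation filter
#'
#' Retains features having at least one proton-adduct annotation.
#'
#' @param table A [feature_table].
#' @param annotations Annotation data frame from [annotate()] computed on
#'   the same table.
#' @return Filtered [feature_table].
#' @export
adduct_filter <- function(table, annotations) {
  stopifnot(inherits(table, "feature_table"))
  if (!nrow(table$features)) return(table)
  subset_features(table,
                  table$features$feature_id %in% annotations$feature_id)
}

#' Apply the full ion-selection cascade with a bookkeeping report
#'
#' Stages run in the order annotation, mean intensity, blank ratio,
#' evidence flag; disabled stages are recorded as pass-throughs so that
#' the report always conserves counts:
#' `count_in = count_out + sum(removed per stage)`.
#'
#' @param table A [feature_table].
#' @param annotations Annotations from [annotate()] (may be NULL when the
#'   annotation stage is disabled).
#' @param config A [filter_config].
#' @return List with elements `table` (the filtered [feature_table]) and
#'   `report` (a `filter_report`).
#' @export
apply_cascade <- function(table, annotations = NULL,
                          config = filter_config()) {
  stopifnot(inherits(table, "feature_table"),
            inherits(config, "filter_config"))
  counts_in <- table(factor(table$features$mode,
                            levels = c("positive", "negative")))
  stage_names <- c("adduct_annotation", "mean_intensity", "blank_ratio",
                   "evidence_flag")
  counts <- integer(0)
  removed <- list()
  cur <- table
  run_stage <- function(name, new_table) {
    gone <- setdiff(cur$features$feature_id, new_table$features$feature_id)
    removed[[name]] <<- gone
    counts[[name]] <<- nrow(new_table$features)
    cur <<- new_table
  }
  run_stage("adduct_annotation",
            if (config$require_adduct_annotation)
              adduct_filter(cur, annotations %||%
                              data.frame(feature_id = character()))
            else cur)
  run_stage("mean_intensity",
            if (config$min_mean_intensity > 0 && nrow(cur$features))
              mean_intensity_filter(cur, config$min_mean_intensity)
            else cur)
  run_stage("blank_ratio",
            if (config$min_blank_ratio > 0 && nrow(cur$features))
              blank_ratio_filter(cur, config$min_blank_ratio)
            else cur)
  run_stage("evidence_flag",
            if (config$require_evidence_flag)
              subset_features(cur, cur$features$evidence_flag)
            else cur)
  report <- structure(list(
    counts_in = as.list(counts_in),
    count_in_total = nrow(table$features),
    stages = stage_names,
    counts_after_each_stage = as.list(counts),
    removed_ids = removed), class = "filter_report")
  list(table = cur, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d ions in (pos %d / neg %d)\n",
              x$count_in_total, x$counts_in$positive, x$counts_in$negative))
  for (s in x$stages)
    cat(sprintf("  after %-18s %6d  (-%d)\n", s,
                x$counts_after_each_stage[[s]], length(x$removed_ids[[s]])))
  invisible(x)
}

#' Serialise a filter report to JSON
#' @param report A `filter_report`.
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
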