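#' Compound databases and ion annotation
#'
#' Features are annotated by matching their adduct-corrected neutral mass
#' against the monoisotopic masses of a compound table (an HMDB-style
#' extract). Positive-mode features are interpreted as `[M+H]+` adducts and
#' negative-mode features as `[M-H]-` adducts; a candidate compound matches
#' when the relative deviation is within `tol_ppm` parts per million.
#'
#' @name annotation
NULL

#' Read a compound table (TSV)
#'
#' Expected columns: `compound_id`, `name`, `formula`,
#' `monoisotopic_mass`. The mass may be empty when a formula is given, in
#' which case it is computed with [monoisotopic_mass()]; when both are
#' present they must agree within 1e-4 Da.
#'
#' @param path Path to the TSV file.
#' @return Data frame of compound records.
#' @export
read_compound_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  needed <- c("compound_id", "name", "formula", "monoisotopic_mass")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    abort_format("compound table '%s' is missing column(s): %s",
                 path, paste(missing_cols, collapse = ", "))
  validate_compound_table(df)
}

validate_compound_table <- function(df) {
  df$formula[is.na(df$formula)] <- ""
  need_mass <- is.na(df$monoisotopic_mass)
  for (i in which(need_mass | nzchar(df$formula))) {
    if (!nzchar(df$formula)[i]) {
      if (need_mass[i])
        abort_validation("compound '%s' has neither formula nor mass",
                         df$compound_id[i])
      next
    }
    m <- monoisotopic_mass(df$formula[i])
    if (need_mass[i]) {
      df$monoisotopic_mass[i] <- m
    } else if (abs(df$monoisotopic_mass[i] - m) > 1e-4) {
      abort_validation(
        "compound '%s': stated mass %.5f disagrees with formula mass %.5f",
        df$compound_id[i], df$monoisotopic_mass[i], m)
    }
  }
  if (any(df$monoisotopic_mass <= 0))
    abort_validation("compound masses must be positive")
  df
}

#' Write a compound table in the package's TSV interchange format
#' @param compounds Compound data frame.
#' @param path Output path.
#' @export
write_compound_table <- function(compounds, path) {
  utils::write.table(
    compounds[, c("compound_id", "name", "formula", "monoisotopic_mass")],
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Annotate features against a compound table
#'
#' Every (feature, compound) pair whose adduct-corrected neutral mass
#' deviation is within `tol_ppm` yields one annotation row. Features may
#' receive zero or several annotations; rows are sorted by feature and
#' then by absolute ppm error, so the first row per feature is its best
#' candidate.
#'
#' @param features A [feature_table] or its `features` data frame
#'   (columns `feature_id`, `mode`, `mz`).
#' @param compounds Compound data frame as from [read_compound_table()].
#' @param tol_ppm Mass tolerance in ppm (default 15).
#' @return Data frame with columns `feature_id`, `compound_id`, `adduct`,
#'   `neutral_mass_obs`, `ppm_error`.
#' @export
annotate <- function(features, compounds, tol_ppm = 15) {
  if (inherits(features, "feature_table")) features <- features$features
  assert_scalar_number(tol_ppm, "tol_ppm", positive = TRUE)
  compounds <- validate_compound_table(as.data.frame(compounds))
  empty <- data.frame(feature_id = character(), compound_id = character(),
                      adduct = character(), neutral_mass_obs = numeric(),
                      ppm_error = numeric(), stringsAsFactors = FALSE)
  if (!nrow(features) || !nrow(compounds)) return(empty)
  out <- vector("list", nrow(features))
  cmass <- compounds$monoisotopic_mass
  for (i in seq_len(nrow(features))) {
    mode <- features$mode[i]
    nm <- neutral_mass_from_mz(features$mz[i], mode)
    ppm <- (nm - cmass) / cmass * 1e6
    hit <- which(abs(ppm) <= tol_ppm)
    if (!length(hit)) next
    hit <- hit[order(abs(ppm[hit]))]
    out[[i]] <- data.frame(
      feature_id = features$feature_id[i],
      compound_id = compounds$compound_id[hit],
      adduct = if (mode == "positive") "[M+H]+" else "[M-H]-",
      neutral_mass_obs = nm,
      ppm_error = ppm[hit],
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}
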