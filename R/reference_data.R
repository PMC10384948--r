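#' Reference per-fold cross-validation metrics
#'
#' Fold-level performance tables of the 15-ion supervised-autoencoder
#' signature workflow on the thyroid FNAC cohort it targets, shipped as
#' plain CSV under `inst/extdata`: twelve stratified repeats for the SAE
#' (per-class accuracies in one table, AUC/precision/recall/F1 in the
#' other) and four repeats for the SVM, PLS-DA and random-forest
#' comparators. They serve as worked-example inputs for
#' [aggregate_metrics()]; aggregating their columns reproduces the
#' workflow's headline mean performance figures (e.g. global accuracy
#' 0.957 and AUC 0.945 for the SAE).
#'
#' @param which One of `"sae_accuracy"`, `"sae_performance"`,
#'   `"comparators"`.
#' @return Data frame of per-fold metrics.
#' @export
reference_fold_metrics <- function(which = c("sae_accuracy",
                                             "sae_performance",
                                             "comparators")) {
  which <- match.arg(which)
  fn <- switch(which,
               sae_accuracy = "sae_fold_accuracy.csv",
               sae_performance = "sae_fold_performance.csv",
               comparators = "comparator_fold_metrics.csv")
  utils::read.csv(system.file("extdata", fn, package = "fnacmet",
                              mustWork = TRUE))
}
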