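#' Repeated stratified evaluation harness
#'
#' Model performance is estimated by Monte-Carlo cross-validation:
#' repeated stratified random train/test splits, per-split metrics
#' (global and per-class accuracy, AUROC, macro precision/recall/F1) and
#' aggregation to mean, SD and range across splits. All compared models
#' run on identical splits.
#'
#' @name evaluation
NULL

#' Build a repeated stratified split plan
#'
#' Each repeat draws a random test set of `round(test_fraction * n)`
#' samples with class proportions preserved to within one sample
#' (largest-remainder allocation per class).
#'
#' @param y Class labels.
#' @param n_repeats Number of repeats.
#' @param test_fraction Fraction of samples held out per repeat.
#' @param seed Seed; the plan is a pure function of `(y, n_repeats,
#'   test_fraction, seed)`.
#' @return A `split_plan`: list with `splits`, each holding `train` and
#'   `test` index vectors.
#' @export
make_splits <- function(y, n_repeats, test_fraction, seed = 1) {
  y <- as.character(y)
  n <- length(y)
  classes <- unique(y)
  if (any(table(y) < 2))
    abort_validation("every class needs at least 2 samples")
  if (test_fraction <= 0 || test_fraction >= 1)
    abort_validation("`test_fraction` must lie in (0, 1)")
  n_test <- round(test_fraction * n)
  # largest-remainder allocation of the test set across classes
  exact <- test_fraction * table(y)[classes]
  base <- floor(exact)
  rem <- n_test - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  if (any(base < 1) || any(base >= table(y)[classes]))
    abort_validation(
      "test_fraction %.2f leaves a class empty in test or train",
      test_fraction)
  splits <- with_seed(seed, lapply(seq_len(n_repeats), function(r) {
    test <- integer(0)
    for (ci in seq_along(classes))
      test <- c(test, sample(which(y == classes[ci]), base[ci]))
    test <- sort(test)
    list(train = setdiff(seq_len(n), test), test = test)
  }))
  structure(list(n_repeats = n_repeats, test_fraction = test_fraction,
                 stratified = TRUE, seed = seed, classes = classes,
                 splits = splits), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$splits, function(s) length(s$test), integer(1))
  cat(sprintf("<split_plan> %d stratified repeats, test sizes %s\n",
              x$n_repeats, paste(unique(sizes), collapse = "/")))
  invisible(x)
}

#' Serialise a split plan to JSON (for cross-method reuse)
#' @param plan A `split_plan`.
#' @param path Output path.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Mann-Whitney concordance AUC; ties count 1/2
concordance_auc <- function(y_true, scores, positive = "malignant") {
  pos <- as.character(y_true) == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-split classification metrics
#'
#' Global accuracy, per-class accuracy (the recall of each class), AUROC
#' as the Mann-Whitney concordance of the malignant score (ties 0.5),
#' and macro-averaged precision, recall and F1 over both classes.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels.
#' @param scores Continuous malignant scores; when `NULL` the AUC is
#'   reported as `NA`.
#' @param positive Positive-class label (default `"malignant"`).
#' @return A one-row data frame of metrics (`fold_metrics`).
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL,
                            positive = "malignant") {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(unique(y_true)) < 2)
    abort_validation("y_true must contain both classes")
  classes <- c(setdiff(unique(y_true), positive)[1L], positive)
  per_class <- lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- tp / (tp + fn)
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  })
  m <- do.call(rbind, per_class)
  data.frame(
    accuracy_global = mean(y_true == y_pred),
    accuracy_benign = m[1L, "recall"],
    accuracy_malignant = m[2L, "recall"],
    auc = if (is.null(scores)) NA_real_ else
      concordance_auc(y_true, scores, positive),
    precision = mean(m[, "precision"]),
    recall = mean(m[, "recall"]),
    f1 = mean(m[, "f1"]))
}

#' Aggregate per-split metrics to mean, SD and range
#'
#' Arithmetic mean and sample SD (n-1 denominator) per metric, with the
#' min/max range. Values are retained at full precision; round for
#' reporting.
#'
#' @param folds Data frame of per-split metrics (rows = splits) or a list
#'   of `fold_metrics` rows.
#' @return Data frame with one row per metric: `mean`, `sd`, `min`, `max`.
#' @export
aggregate_metrics <- function(folds) {
  if (is.list(folds) && !is.data.frame(folds))
    folds <- do.call(rbind, folds)
  if (is.null(folds) || !nrow(folds))
    abort_validation("no fold metrics to aggregate")
  if (nrow(folds) < 2)
    abort_validation("aggregation needs at least 2 folds")
  num <- folds[, vapply(folds, is.numeric, logical(1)), drop = FALSE]
  data.frame(metric = names(num),
             mean = vapply(num, function(v) mean(v, na.rm = TRUE),
                           numeric(1)),
             sd = vapply(num, function(v) stats::sd(v, na.rm = TRUE),
                         numeric(1)),
             min = vapply(num, function(v) suppressWarnings(
               min(v, na.rm = TRUE)), numeric(1)),
             max = vapply(num, function(v) suppressWarnings(
               max(v, na.rm = TRUE)), numeric(1)),
             row.names = NULL)
}

#' Built-in model registry
#'
#' Uniform train/predict wrappers for the four compared classifiers: the
#' package's supervised autoencoder and PLS-DA, plus radial-kernel SVM
#' (\pkg{e1071}) and random forest (\pkg{randomForest}) as standard
#' comparators. Each entry has `fit(X, y)` returning an opaque model and
#' `predict(model, X)` returning `list(class=, score=)` where `score` is
#' a continuous malignant score.
#'
#' @param sae_cfg An [sae_config()] for the SAE entry.
#' @param plsda_components Component count for the PLS-DA entry.
#' @return Named list of model wrappers.
#' @export
model_registry <- function(sae_cfg = sae_config(),
                          plsda_components = 2) {
  list(
    sae = list(
      fit = function(X, y) fit_sae(X, y, sae_cfg),
      predict = function(m, X)
        list(class = predict_sae(m, X), score = predict_proba(m, X))),
    plsda = list(
      fit = function(X, y)
        fit_plsda(X, y, A = min(plsda_components, ncol(X), nrow(X) - 1L)),
      predict = function(m, X) {
        pr <- predict(m, X)
        list(class = pr$class, score = pr$score)
      }),
    svm = list(
      fit = function(X, y)
        e1071::svm(X, factor(y), kernel = "radial", probability = TRUE),
      predict = function(m, X) {
        pr <- predict(m, X, probability = TRUE)
        prob <- attr(pr, "probabilities")[, "malignant"]
        list(class = as.character(pr), score = prob)
      }),
    rf = list(
      fit = function(X, y) randomForest::randomForest(X, factor(y)),
      predict = function(m, X) {
        prob <- predict(m, X, type = "prob")[, "malignant"]
        list(class = as.character(predict(m, X)), score = prob)
      }))
}

#' Compare classifiers on identical splits
#'
#' Fits every registry model on each training split and evaluates it on
#' the matching test split. The feature matrix is fixed before the
#' comparison (frozen-signature mode): when the signature was selected on
#' the full data set, the resulting estimates are optimistic, which is
#' why [honest_signature_cv()] exists as the leakage-free alternative.
#' A model failing on a split is recorded as a missing fold with a
#' warning and excluded from that model's aggregation.
#'
#' @param X Samples x features matrix (standardised log scale).
#' @param y Class labels.
#' @param plan A `split_plan` from [make_splits()].
#' @param registry Model registry, default [model_registry()].
#' @param seed Seed fixed around each model fit, so stochastic learners
#'   are reproducible.
#' @return A `comparison_table`: list with per-method `folds` data frames
#'   and `aggregate` tables.
#' @export
compare_models <- function(X, y, plan, registry = model_registry(),
                           seed = 1) {
  stopifnot(inherits(plan, "split_plan"))
  X <- as.matrix(X)
  y <- as.character(y)
  folds <- list(); aggregates <- list()
  for (mname in names(registry)) {
    entry <- registry[[mname]]
    rows <- vector("list", plan$n_repeats)
    for (r in seq_len(plan$n_repeats)) {
      sp <- plan$splits[[r]]
      rows[[r]] <- tryCatch({
        m <- with_seed(derive_seed(seed, r), entry$fit(
          X[sp$train, , drop = FALSE], y[sp$train]))
        pr <- entry$predict(m, X[sp$test, , drop = FALSE])
        cbind(data.frame(method = mname, fold = r),
              compute_metrics(y[sp$test], pr$class, pr$score))
      }, error = function(e) {
        warning(sprintf("method '%s' failed on split %d: %s",
                        mname, r, conditionMessage(e)))
        NULL
      })
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    fd <- do.call(rbind, rows)
    folds[[mname]] <- fd
    aggregates[[mname]] <- aggregate_metrics(fd)
  }
  structure(list(folds = folds, aggregate = aggregates, plan = plan),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("<comparison_table> %d methods x %d splits\n",
              length(x$folds), x$plan$n_repeats))
  for (m in names(x$aggregate)) {
    ag <- x$aggregate[[m]]
    acc <- ag$mean[ag$metric == "accuracy_global"]
    auc <- ag$mean[ag$metric == "auc"]
    f1 <- ag$mean[ag$metric == "f1"]
    cat(sprintf("  %-6s accuracy %.3f  AUC %.3f  F1 %.3f\n",
                m, acc, auc, f1))
  }
  invisible(x)
}

#' Write a comparison table as a long CSV (method x metric rows)
#' @param comparison A `comparison_table`.
#' @param path Output CSV path; per-fold metrics go to a `_folds.csv`
#'   twin.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "comparison_table"))
  agg <- do.call(rbind, lapply(names(comparison$aggregate), function(m)
    cbind(method = m, comparison$aggregate[[m]])))
  utils::write.csv(agg, path, row.names = FALSE)
  fd <- do.call(rbind, comparison$folds)
  utils::write.csv(fd, sub("\\.csv$", "_folds.csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' Honest per-split signature re-selection
#'
#' Leakage-free counterpart of the frozen-signature comparison: within
#' each training split the top-down SAE selection is re-run from the full
#' feature set, and only the selected ions are used to fit and test. On
#' null data this yields chance-level accuracy, quantifying the optimism
#' of selecting a signature once on all samples.
#'
#' @param X Samples x full-feature matrix (standardised log scale).
#' @param y Class labels.
#' @param plan A `split_plan`.
#' @param k Signature size per split.
#' @param config [sae_config()] used for selection and the final fit.
#' @return Data frame of per-split metrics.
#' @export
honest_signature_cv <- function(X, y, plan, k = 15,
                                config = sae_config()) {
  stopifnot(inherits(plan, "split_plan"))
  X <- as.matrix(X)
  rows <- vector("list", plan$n_repeats)
  for (r in seq_len(plan$n_repeats)) {
    sp <- plan$splits[[r]]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, r)
    sig <- topdown_select(X[sp$train, , drop = FALSE], y[sp$train],
                          k = k, config = cfg)
    feats <- sig$entries$feature_id
    pr <- predict_sae(sig$model, X[sp$test, feats, drop = FALSE])
    sc <- predict_proba(sig$model, X[sp$test, feats, drop = FALSE])
    rows[[r]] <- cbind(data.frame(fold = r),
                       compute_metrics(y[sp$test], pr, sc))
  }
  do.call(rbind, rows)
}
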