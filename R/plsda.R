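#' Partial least squares discriminant analysis
#'
#' Two-class PLS-DA fitted by the NIPALS PLS1 algorithm on a +/-1 class
#' coding: components maximise covariance between the data and the coded
#' response, the response and data matrices being deflated after each
#' component. Prediction is the sign of the regression output (threshold
#' 0; an exact 0 is resolved to the benign majority class). Goodness of
#' fit (R2) is the cumulative fraction of response variance explained on
#' the training data; goodness of prediction (Q2) is `1 - PRESS/TSS`
#' using cross-validated held-out predictions.
#'
#' @name plsda
NULL

code_classes <- function(y) {
  y <- as.character(y)
  classes <- c("benign", "malignant")
  if (!all(y %in% classes)) classes <- sort(unique(y))
  if (length(unique(y)) != 2L)
    abort_validation("PLS-DA needs exactly two classes, got: %s",
                     paste(unique(y), collapse = ", "))
  list(classes = classes, coded = ifelse(y == classes[2L], 1, -1))
}

#' Fit a PLS-DA model
#'
#' @param X Numeric matrix, samples x features (typically already
#'   standardised; the fit centres columns internally either way).
#' @param y Class labels, two classes; `"malignant"` is coded +1.
#' @param A Number of latent components.
#' @return A `plsda_model`.
#' @export
fit_plsda <- function(X, y, A = 2) {
  X <- as.matrix(X)
  cc <- code_classes(y)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) abort_validation("X and y lengths differ")
  tab <- table(cc$coded)
  if (any(tab < 2)) abort_validation("each class needs at least 2 samples")
  if (A < 1 || A > min(p, n - 1))
    abort_validation("A must lie in 1..min(features, samples-1)")

  x_mean <- colMeans(X)
  y_mean <- mean(cc$coded)
  E <- sweep(X, 2L, x_mean)
  f <- cc$coded - y_mean
  tss <- sum(f^2)

  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A); ss <- numeric(A)
  a_used <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    p_a <- drop(crossprod(E, t_a)) / tt
    q_a <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p_a)
    f <- f - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
    q[a] <- q_a; ss[a] <- q_a^2 * tt
    a_used <- a
  }
  if (a_used == 0L)
    abort_validation("PLS-DA found no usable component (X'y is null)")
  W <- W[, 1:a_used, drop = FALSE]; P <- P[, 1:a_used, drop = FALSE]
  Tm <- Tm[, 1:a_used, drop = FALSE]
  q <- q[1:a_used]; ss <- ss[1:a_used]
  B <- W %*% solve(crossprod(P, W), q)
  structure(list(n_components = a_used, weights = W, loadings = P,
                 scores = Tm, q = q, ss = ss, coefficients = drop(B),
                 x_mean = x_mean, y_mean = y_mean,
                 classes = cc$classes, tss = tss,
                 R2 = cumsum(ss) / tss,
                 feature_names = colnames(X)),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d components, %d features; R2 = %s\n",
              x$n_components, length(x$coefficients),
              paste(sprintf("%.3f", x$R2), collapse = " ")))
  invisible(x)
}

#' Predict from a PLS-DA model
#' @param object A `plsda_model`.
#' @param newdata Samples x features matrix.
#' @param ... Unused.
#' @return List with `score` (continuous regression output) and `class`.
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  score <- drop(sweep(newdata, 2L, object$x_mean) %*% object$coefficients) +
    object$y_mean
  cls <- ifelse(score > 0, object$classes[2L], object$classes[1L])
  list(score = score, class = cls)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a SS_a w_ja^2 / sum_a SS_a)` with unit-norm
#' weight vectors and `SS_a` the response sum of squares explained by
#' component `a`. The mean of the squared VIPs is exactly 1.
#'
#' @param model A `plsda_model`.
#' @return Named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  ss_tot <- sum(model$ss)
  if (ss_tot <= 0) abort_validation("model explains zero response variance")
  p <- nrow(model$weights)
  v <- sqrt(p * drop(model$weights^2 %*% model$ss) / ss_tot)
  names(v) <- model$feature_names
  v
}

stratified_fold_ids <- function(y, folds, seed) {
  y <- as.character(y)
  if (folds < 2) abort_validation("`folds` must be at least 2")
  if (min(table(y)) < folds)
    abort_validation("folds (%d) exceed the smallest class size", folds)
  id <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  id
}

#' Cross-validated PLS-DA performance
#'
#' Stratified k-fold cross-validation with per-fold re-centring and
#' re-scaling of the columns (training statistics only, no leakage).
#' Reports, per component count: training R2 (from a full-data fit),
#' cross-validated Q2 and classification accuracy. The reported model
#' size is the component count with the best R2 (smallest such count on
#' ties), alongside the full curves.
#'
#' @param X Samples x features matrix (log-scale; scaling is handled
#'   per fold).
#' @param y Two-class labels.
#' @param A_max Largest component count to evaluate.
#' @param folds Number of folds (default 10).
#' @param seed Seed for the fold draw.
#' @param scale Re-scale columns per fold (default TRUE).
#' @return A `plsda_performance` list with `accuracy`, `R2`, `Q2`,
#'   `best_A` and a `curves` data frame.
#' @export
cross_validate_plsda <- function(X, y, A_max = 5, folds = 10, seed = 1,
                                 scale = TRUE) {
  X <- as.matrix(X)
  cc <- code_classes(y)
  n <- nrow(X)
  A_max <- min(A_max, ncol(X), n - 2L)
  if (A_max < 1) abort_validation("A_max must be at least 1")
  fold_id <- stratified_fold_ids(cc$coded, folds, seed)

  press <- numeric(A_max)
  correct <- matrix(0, n, A_max)
  for (k in seq_len(folds)) {
    te <- fold_id == k
    Xtr <- X[!te, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    ctr <- colMeans(Xtr)
    str <- if (scale) pmax(apply(Xtr, 2L, stats::sd), 1e-12) else
      rep(1, ncol(Xtr))
    Xtr <- sweep(sweep(Xtr, 2L, ctr), 2L, str, "/")
    Xte <- sweep(sweep(Xte, 2L, ctr), 2L, str, "/")
    m <- fit_plsda(Xtr, cc$classes[(cc$coded[!te] > 0) + 1L],
                   A = min(A_max, nrow(Xtr) - 1L))
    # per-component cumulative predictions on the held-out fold
    Ete <- sweep(Xte, 2L, m$x_mean)
    yhat <- rep(m$y_mean, nrow(Xte))
    for (a in seq_len(m$n_components)) {
      t_te <- drop(Ete %*% m$weights[, a])
      yhat <- yhat + t_te * m$q[a]
      Ete <- Ete - tcrossprod(t_te, m$loadings[, a])
      press[a] <- press[a] + sum((cc$coded[te] - yhat)^2)
      correct[te, a] <- (yhat > 0) == (cc$coded[te] > 0)
    }
    if (m$n_components < A_max)
      for (a in (m$n_components + 1):A_max) {
        press[a] <- press[a] + sum((cc$coded[te] - yhat)^2)
        correct[te, a] <- (yhat > 0) == (cc$coded[te] > 0)
      }
  }
  tss <- sum((cc$coded - mean(cc$coded))^2)
  q2 <- 1 - press / tss

  Xs <- if (scale)
    sweep(sweep(X, 2L, colMeans(X)), 2L,
          pmax(apply(X, 2L, stats::sd), 1e-12), "/") else X
  full <- fit_plsda(Xs, y, A = A_max)
  r2 <- full$R2
  if (length(r2) < A_max) r2 <- c(r2, rep(r2[length(r2)], A_max - length(r2)))
  acc <- colMeans(correct)
  best_A <- which.max(r2)
  structure(list(accuracy = acc[best_A], R2 = r2[best_A], Q2 = q2[best_A],
                 best_A = best_A, folds = folds,
                 curves = data.frame(A = seq_len(A_max), R2 = r2, Q2 = q2,
                                     accuracy = acc),
                 model = full),
            class = "plsda_performance")
}

#' @export
print.plsda_performance <- function(x, ...) {
  cat(sprintf(
    "<plsda_performance> best A = %d: accuracy %.3f, R2 %.3f, Q2 %.3f\n",
    x$best_A, x$accuracy, x$R2, x$Q2))
  invisible(x)
}

#' Label-permutation significance test
#'
#' The observed statistic is the cross-validated accuracy of the PLS-DA
#' model; the null distribution is rebuilt by refitting on permuted class
#' labels. The p-value uses the add-one rule
#' `(1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param X Samples x features matrix.
#' @param y Two-class labels.
#' @param A Component count of the tested model.
#' @param n_perm Number of permutations (default 2000).
#' @param seed Seed controlling fold draws and permutations.
#' @param folds Folds for the inner cross-validation (default 5).
#' @return A `permutation_result` list.
#' @export
permutation_test <- function(X, y, A = 2, n_perm = 2000, seed = 1,
                             folds = 5) {
  if (!is.numeric(n_perm) || n_perm < 1)
    abort_validation("`n_perm` must be at least 1")
  stat <- function(yy, s) {
    cv <- cross_validate_plsda(X, yy, A_max = A, folds = folds, seed = s)
    cv$curves$accuracy[min(A, nrow(cv$curves))]
  }
  observed <- stat(y, derive_seed(seed, 0L))
  null_stats <- numeric(n_perm)
  perms <- with_seed(seed, replicate(n_perm, sample(length(y)),
                                     simplify = FALSE))
  for (b in seq_len(n_perm))
    null_stats[b] <- stat(y[perms[[b]]], derive_seed(seed, b))
  p <- (1 + sum(null_stats >= observed)) / (n_perm + 1)
  structure(list(n_permutations = n_perm, observed_statistic = observed,
                 null_statistics = null_stats, p_value = p),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed %.3f vs %d permutations: p = %.4g\n",
    x$observed_statistic, x$n_permutations, x$p_value))
  invisible(x)
}
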