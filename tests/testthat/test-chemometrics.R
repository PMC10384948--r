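# Normalisation, NIPALS PLS-DA, VIP scores, CV and permutation testing.

test_that("normalisation standardises training columns and inverts", {
  fx <- get_fixture()
  tab <- subset_features(fx$truth_table, 1:40)
  norm <- normalize_intensities(tab)
  expect_equal(unname(rowMeans(norm$values)), rep(0, 40),
               tolerance = 1e-8)
  sds <- apply(norm$values, 1, sd)
  expect_equal(unname(sds), rep(1, 40), tolerance = 1e-8)
  # algebraic inverse reproduces the imputed log10 intensities
  sc <- which(tab$samples$role == "sample")
  mat <- tab$intensities[, sc, drop = FALSE]
  zero <- mat == 0
  mat[zero] <- norm$log_offset[row(mat)[zero]]
  expect_equal(unname(denormalize(norm)), unname(log10(mat)),
               tolerance = 1e-12)
})

test_that("normalisation handles degenerate features and rejects dead ones", {
  tab <- make_toy_table(matrix(c(rep(100, 4), rep(0, 4)), 2, 4,
                               byrow = TRUE))
  expect_error(normalize_intensities(tab), "F002",
               class = "fnacmet_validation_error")
  const <- make_toy_table(matrix(100, 1, 4))
  norm <- normalize_intensities(const)
  expect_equal(unname(norm$values[1, ]), rep(0, 4))
})

test_that("held-out samples are transformed with training parameters", {
  fx <- get_fixture()
  tab <- subset_features(fx$truth_table, 1:20)
  ids <- tab$samples$run_id[tab$samples$role == "sample"]
  train_ids <- ids[1:50]
  norm <- normalize_intensities(tab, training_ids = train_ids)
  tr <- norm$samples$run_id %in% train_ids
  expect_equal(unname(rowMeans(norm$values[, tr])), rep(0, 20),
               tolerance = 1e-8)
  # mapping the raw test columns reproduces the stored test columns
  sc <- which(tab$samples$role == "sample")
  raw_test <- tab$intensities[, sc[!tr], drop = FALSE]
  expect_equal(apply_normalization(norm, raw_test),
               norm$values[, !tr], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("PLS-DA separates a separable toy and rejects bad input", {
  toy <- make_separable_toy(10, p = 2, sd = 0.1)
  m <- fit_plsda(toy$X, toy$y, A = 1)
  expect_equal(mean(predict(m, toy$X)$class == toy$y), 1.0)
  expect_error(fit_plsda(toy$X, rep("benign", 20), A = 1),
               class = "fnacmet_validation_error")
  expect_error(fit_plsda(toy$X, toy$y, A = 25),
               class = "fnacmet_validation_error")
})

test_that("one-component single-feature PLS equals univariate least squares", {
  set.seed(3)
  x <- matrix(rnorm(30), 30, 1)
  y <- ifelse(x + rnorm(30, 0, 0.5) > 0, "malignant", "benign")
  m <- fit_plsda(x, y, A = 1)
  yc <- ifelse(y == "malignant", 1, -1)
  beta <- drop(cov(x[, 1], yc)) / drop(var(x[, 1]))
  pred_ls <- mean(yc) + (x[, 1] - mean(x[, 1])) * beta
  expect_equal(predict(m, x)$score, pred_ls, tolerance = 1e-10)
})

test_that("PLS-DA equals least squares on the Krylov subspace", {
  # brute-force oracle on tiny problems: the A-component PLS coefficient
  # vector is the least-squares solution restricted to the Krylov space
  # spanned by X'y, (X'X)X'y, ...
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(8:12, 1); p <- sample(3:5, 1)
    A <- sample(1:min(3, p), 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(c("benign", "malignant"), n, replace = TRUE,
                prob = c(0.6, 0.4))
    if (length(unique(y)) < 2 || min(table(y)) < 2) next
    m <- fit_plsda(X, y, A = A)
    yc <- ifelse(y == "malignant", 1, -1)
    Xc <- scale(X, scale = FALSE)
    fc <- yc - mean(yc)
    K <- matrix(0, p, A)
    v <- crossprod(Xc, fc)
    for (a in seq_len(A)) {
      K[, a] <- v
      v <- crossprod(Xc, Xc %*% v)
    }
    beta_k <- K %*% solve(crossprod(Xc %*% K), crossprod(Xc %*% K, fc))
    expect_equal(drop(Xc %*% m$coefficients[seq_len(p)]),
                 drop(Xc %*% beta_k), tolerance = 1e-6)
  }
})

test_that("VIP scores satisfy their normalisation identity", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 20; p <- sample(c(5, 15, 40), 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c("benign", "malignant"), c(12, 8))
    m <- fit_plsda(X, y, A = sample(1:3, 1))
    v <- vip_scores(m)
    expect_equal(mean(v^2), 1, tolerance = 1e-10)
  }
  # single component: VIP reduces to sqrt(p) * |w|
  toy <- make_separable_toy(8, p = 4, sd = 0.5, seed = 2)
  m1 <- fit_plsda(toy$X, toy$y, A = 1)
  expect_equal(unname(vip_scores(m1)), sqrt(4) * abs(m1$weights[, 1]),
               tolerance = 1e-12)
})

test_that("VIP ranks planted informative features highly", {
  hits <- 0L
  n_rep <- 20L
  for (seed in seq_len(n_rep)) {
    set.seed(seed)
    n <- 40; p <- 50
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c("benign", "malignant"), each = 20)
    X[y == "malignant", 1:5] <- X[y == "malignant", 1:5] + 1.8
    m <- fit_plsda(scale(X), y, A = 2)
    top10 <- order(-vip_scores(m))[1:10]
    if (all(1:5 %in% top10)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("cross-validated Q2 is negative on noise, high on signal", {
  q2_noise <- sapply(1:20, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(40 * 10), 40, 10)
    y <- rep(c("benign", "malignant"), each = 20)
    cross_validate_plsda(X, y, A_max = 3, folds = 5, seed = seed)$Q2
  })
  expect_lte(median(q2_noise), 0)

  md <- get_fixture_model_data()
  Xs <- md$X[, md$informative]
  cv <- cross_validate_plsda(Xs, md$y, A_max = 5, folds = 10, seed = 4)
  expect_gt(cv$Q2, 0.5)
  expect_gte(cv$R2, cv$Q2)
  expect_lte(cv$R2, 1)
})

test_that("permutation test applies the add-one rule and detects signal", {
  expect_error(permutation_test(matrix(rnorm(20), 10, 2),
                                rep(c("benign", "malignant"), 5),
                                n_perm = 0),
               class = "fnacmet_validation_error")
  md <- get_fixture_model_data()
  Xs <- md$X[, md$informative]
  res <- permutation_test(Xs, md$y, A = 2, n_perm = 99, seed = 5)
  expect_equal(res$p_value,
               (1 + sum(res$null_statistics >= res$observed_statistic)) /
                 (99 + 1))
  expect_lt(res$p_value, 0.05)
  expect_length(res$null_statistics, 99)
})
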