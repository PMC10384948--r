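# Supervised autoencoder: training, scores, confidence, selection.

test_that("training is bitwise deterministic given the seed", {
  toy <- make_separable_toy(6, p = 5, sd = 0.5)
  cfg <- sae_config(hidden_sizes = 8, epochs = 30, seed = 99)
  m1 <- fit_sae(toy$X, toy$y, cfg)
  m2 <- fit_sae(toy$X, toy$y, cfg)
  expect_identical(m1$encoder, m2$encoder)
  expect_identical(m1$decoder, m2$decoder)
  expect_identical(m1$classifier, m2$classifier)
  expect_identical(m1$loss_trace, m2$loss_trace)
  m3 <- fit_sae(toy$X, toy$y, sae_config(hidden_sizes = 8, epochs = 30,
                                         seed = 100))
  expect_false(identical(m1$encoder, m3$encoder))
})

test_that("with no reconstruction term the SAE is a plain classifier", {
  toy <- make_separable_toy(8, p = 4, sd = 0.1)
  m <- fit_sae(toy$X, toy$y, sae_config(hidden_sizes = 8, epochs = 150,
                                        recon_weight = 0, seed = 1))
  expect_equal(mean(predict_sae(m, toy$X) == toy$y), 1.0)
})

test_that("an overwhelming reconstruction weight suppresses classification", {
  # class signal lives on a low-variance axis; five high-variance nuisance
  # axes dominate the reconstruction objective, so a huge lambda starves
  # the 2-D latent of class information
  set.seed(2)
  n <- 20
  X <- cbind(matrix(rnorm(n * 5, 0, 3), n, 5),
             rep(c(-1, 1), each = n / 2) + rnorm(n, 0, 0.1))
  colnames(X) <- sprintf("f%02d", 1:6)
  y <- rep(c("benign", "malignant"), each = n / 2)
  cfg0 <- sae_config(hidden_sizes = 8, epochs = 150, recon_weight = 0,
                     seed = 1)
  cfg_big <- sae_config(hidden_sizes = 8, epochs = 150,
                        recon_weight = 1e3, seed = 1)
  acc0 <- mean(predict_sae(fit_sae(X, y, cfg0), X) == y)
  acc_big <- mean(predict_sae(fit_sae(X, y, cfg_big), X) == y)
  expect_equal(acc0, 1.0)
  expect_lt(acc_big, 0.8)
})

test_that("probabilities come from a two-logit softmax", {
  # hand-built model: zero encoder -> zero latent -> zero logits -> 0.5
  W1 <- matrix(0, 3, 4); W2 <- matrix(0, 4, 2)
  m <- manual_sae(W1, rep(0, 4), W2, rep(0, 2),
                  Wc = matrix(0, 2, 2), bc = c(0, 0))
  X <- matrix(rnorm(9), 3, 3)
  expect_equal(predict_proba(m, X), rep(0.5, 3))
  expect_equal(predict_sae(m, X), rep("benign", 3))  # tie goes to benign
  # shifting the malignant bias moves every probability up
  m$classifier[[1]]$b <- c(0, 1)
  expect_true(all(predict_proba(m, X) > 0.5))
})

test_that("latent projection is deterministic with the right shape", {
  toy <- make_separable_toy(6, p = 5, sd = 0.3)
  m <- fit_sae(toy$X, toy$y, sae_config(hidden_sizes = 8, epochs = 30,
                                        seed = 2))
  L <- project_latent(m, toy$X)
  expect_equal(dim(L), c(12L, 2L))
  X2 <- toy$X[c(1, 1, 5), ]
  L2 <- project_latent(m, X2)
  expect_equal(L2[1, ], L2[2, ])
  expect_error(project_latent(m, toy$X[, 1:3]),
               class = "fnacmet_validation_error")
})

test_that("feature scores equal the input gradient of the logit difference", {
  set.seed(8)
  W1 <- matrix(rnorm(5 * 4, sd = 0.5), 5, 4)
  W2 <- matrix(rnorm(4 * 2, sd = 0.5), 4, 2)
  Wc <- matrix(rnorm(4), 2, 2)
  m <- manual_sae(W1, rnorm(4), W2, rnorm(2), Wc, rnorm(2))
  X <- matrix(rnorm(3 * 5), 3, 5)
  sc <- feature_scores(m, X)
  # finite-difference oracle
  logit_diff <- function(X) {
    L <- project_latent(m, X)
    lg <- sweep(L %*% m$classifier[[1]]$W, 2, m$classifier[[1]]$b, `+`)
    lg[, 2] - lg[, 1]
  }
  h <- 1e-6
  fd <- sapply(seq_len(5), function(j) {
    Xp <- X; Xp[, j] <- Xp[, j] + h
    Xm <- X; Xm[, j] <- Xm[, j] - h
    mean((logit_diff(Xp) - logit_diff(Xm)) / (2 * h))
  })
  expect_equal(unname(sc), fd, tolerance = 1e-5)
})

test_that("dead inputs score zero and duplicated inputs score equally", {
  set.seed(9)
  W1 <- matrix(rnorm(4 * 3), 4, 3)
  W1[2, ] <- 0                 # feature 2 never enters the encoder
  W1[4, ] <- W1[1, ]           # feature 4 duplicates feature 1's wiring
  W2 <- matrix(rnorm(3 * 2), 3, 2)
  m <- manual_sae(W1, rnorm(3), W2, rnorm(2),
                  Wc = matrix(rnorm(4), 2, 2), bc = rnorm(2))
  X <- matrix(rnorm(6 * 4), 6, 4)
  X[, 4] <- X[, 1]
  sc <- feature_scores(m, X)
  expect_equal(unname(sc[2]), 0)
  expect_equal(unname(sc[1]), unname(sc[4]), tolerance = 1e-6)
})

test_that("confidence curves integrate to one and honour symmetry", {
  probs <- c(0.2, 0.4, 0.5, 0.6, 0.8, 0.5)
  y <- c("benign", "benign", "benign", "malignant", "malignant",
         "malignant")
  cc <- confidence_curves(probs, y)
  trap <- function(d) sum(diff(cc$grid) * (head(d, -1) + tail(d, -1)) / 2)
  expect_equal(trap(cc$density_benign), 1, tolerance = 1e-3)
  expect_equal(trap(cc$density_malignant), 1, tolerance = 1e-3)
  # the two 0.5 samples sit at the crossing of two mirror-image densities
  expect_equal(cc$confidence[3], 0.5, tolerance = 1e-9)
  expect_equal(cc$confidence[6], 0.5, tolerance = 1e-9)
})

test_that("disjoint probability supports give total confidence", {
  probs <- c(rep(0, 4), rep(1, 3))
  y <- c(rep("benign", 4), rep("malignant", 3))
  cc <- confidence_curves(probs, y)
  expect_equal(cc$confidence, rep(1, 7), tolerance = 1e-6)
  expect_true(all(cc$bandwidths >= 1e-3))
})

test_that("benign/malignant ratios behave as effect-size summaries", {
  roles <- rep("sample", 6)
  labels <- rep(c("benign", "malignant"), each = 3)
  tab <- make_toy_table(rbind(c(10, 10, 10, 10, 10, 10),
                              c(70, 70, 70, 10, 10, 10),
                              c(5, 5, 5, 0, 0, 0)),
                        roles = roles, labels = labels)
  expect_equal(bm_ratio(tab, "F001"), 1.0)
  expect_equal(bm_ratio(tab, "F002"), 7.0)
  expect_warning(r <- bm_ratio(tab, "F003"), "zero")
  expect_identical(r, Inf)
  # swapping the labels inverts the ratio
  tab2 <- tab
  tab2$samples$class_label <- rev(labels)
  expect_equal(bm_ratio(tab2, "F002"), 1 / 7, tolerance = 1e-12)
})

test_that("top-down selection obeys its schedule and preconditions", {
  toy <- make_separable_toy(8, p = 16, sd = 1, seed = 4)
  cfg <- sae_config(hidden_sizes = 8, epochs = 40, seed = 1)
  sig <- topdown_select(toy$X, toy$y, k = 15, config = cfg,
                        n_scoring_fits = 1)
  expect_equal(sig$history, c(16L, 15L))
  expect_equal(nrow(sig$entries), 15L)
  expect_true(all(diff(sig$entries$sae_score) <= 0))
  expect_error(topdown_select(toy$X, toy$y, k = 16, config = cfg),
               class = "fnacmet_validation_error")
  expect_error(topdown_select(toy$X, toy$y, k = 5, drop_fraction = 0,
                              config = cfg),
               class = "fnacmet_validation_error")
})

test_that("selection recovers planted features on the miniature cohort", {
  md <- get_fixture_model_data()
  cfg <- sae_config(seed = 7)
  sig <- topdown_select(md$X, md$y, k = 15, config = cfg,
                        table = md$table)
  rec <- sum(sig$entries$feature_id %in% md$informative)
  expect_gte(rec, 10)
  # signature rows carry positive B/M ratios from the raw table
  expect_true(all(sig$entries$bm_ratio > 0))
  # latent space separates the classes better than chance: silhouette-like
  # centroid separation at least twice the mean within-class spread
  L <- project_latent(sig$model, md$X[, sig$entries$feature_id])
  cb <- colMeans(L[md$y == "benign", , drop = FALSE])
  cm <- colMeans(L[md$y == "malignant", , drop = FALSE])
  within <- mean(c(sqrt(rowSums(sweep(L[md$y == "benign", ], 2, cb)^2)),
                   sqrt(rowSums(sweep(L[md$y == "malignant", ], 2,
                                      cm)^2))))
  expect_gt(sqrt(sum((cb - cm)^2)), 2 * within)
})

test_that("confidence is higher for correct than for wrong predictions", {
  md <- get_fixture_model_data()
  set.seed(21)
  test_idx <- c(sample(which(md$y == "benign"), 14),
                sample(which(md$y == "malignant"), 6))
  train_idx <- setdiff(seq_along(md$y), test_idx)
  Xs <- md$X[, md$informative]
  m <- fit_sae(Xs[train_idx, ], md$y[train_idx], sae_config(seed = 3))
  pr <- predict_proba(m, Xs)
  cc <- confidence_curves(pr, md$y)
  wrong <- predict_sae(m, Xs) != md$y
  if (any(wrong))
    expect_gt(mean(cc$confidence[!wrong]), mean(cc$confidence[wrong]))
  # holdout errors stay rare in this regime
  expect_lte(sum(predict_sae(m, Xs[test_idx, ]) != md$y[test_idx]), 3)
})
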