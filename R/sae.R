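#' Supervised autoencoder
#'
#' A small dense neural network trained to minimise a class-weighted
#' cross-entropy on a two-logit classifier attached to the latent layer,
#' plus `lambda` times the mean-squared reconstruction error of a mirror
#' decoder. The latent space is low-dimensional (2 by default) so that
#' samples can be inspected directly; the reconstruction term regularises
#' the encoder towards representations that retain the metabolomic
#' profile rather than only the decision boundary. Training is plain
#' minibatch Adam and is bitwise reproducible given the seed: the
#' parameter initialisation and the batch order are both drawn from a
#' private RNG stream.
#'
#' @name sae
NULL

#' SAE hyperparameters
#'
#' @param hidden_sizes Integer vector of encoder hidden-layer widths
#'   (mirrored by the decoder). Default 64.
#' @param latent_dim Latent dimension, at least 2 (default 2).
#' @param recon_weight Weight `lambda` of the reconstruction loss
#'   (default 0.1). 0 reduces the model to a plain classifier.
#' @param learning_rate Adam step size (default 0.01; chosen so the
#'   network trains to convergence within the default epoch budget on
#'   cohorts of tens of samples and hundreds to thousands of ions).
#' @param epochs Training epochs (default 300).
#' @param batch_size Minibatch size (default 16).
#' @param seed Seed for initialisation and batch order (default 1).
#' @param class_weights Named per-class positive weights; default inverse
#'   class frequency, so the minority malignant class is up-weighted.
#' @return An `sae_config` list.
#' @export
sae_config <- function(hidden_sizes = 64, latent_dim = 2,
                       recon_weight = 0.1, learning_rate = 0.01,
                       epochs = 300, batch_size = 16, seed = 1,
                       class_weights = NULL) {
  if (latent_dim < 2) abort_validation("`latent_dim` must be at least 2")
  if (epochs < 1) abort_validation("`epochs` must be at least 1")
  if (recon_weight < 0) abort_validation("`recon_weight` must be >= 0")
  assert_scalar_number(learning_rate, "learning_rate", positive = TRUE)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 latent_dim = as.integer(latent_dim),
                 recon_weight = recon_weight,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 class_weights = class_weights),
            class = "sae_config")
}

init_layer <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)),
                  n_in, n_out),
       b = rep(0, n_out))
}

# forward through a stack of layers; ReLU on all but the last
stack_forward <- function(X, layers) {
  A <- X
  Zs <- vector("list", length(layers))
  As <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    Z <- sweep(A %*% layers[[l]]$W, 2L, layers[[l]]$b, `+`)
    Zs[[l]] <- Z
    A <- if (l < length(layers)) pmax(Z, 0) else Z
    As[[l]] <- A
  }
  list(out = A, Zs = Zs, As = As)
}

# backward through a stack; G is the gradient at the stack output.
# Returns per-layer gradients and the gradient at the stack input.
stack_backward <- function(X, layers, fwd, G) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    A_prev <- if (l == 1L) X else fwd$As[[l - 1L]]
    grads[[l]] <- list(W = crossprod(A_prev, G), b = colSums(G))
    G <- G %*% t(layers[[l]]$W)
    if (l > 1L) G <- G * (fwd$Zs[[l - 1L]] > 0)
  }
  list(grads = grads, G_input = G)
}

adam_init <- function(layers)
  lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (l in seq_along(layers)) {
    st <- state[[l]]; g <- grads[[l]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    layers[[l]]$W <- layers[[l]]$W - lr * (st$mW / c1) /
      (sqrt(st$vW / c2) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * (st$mb / c1) /
      (sqrt(st$vb / c2) + eps)
    state[[l]] <- st
  }
  list(layers = layers, state = state)
}

softmax2 <- function(logits) {
  m <- pmax(logits[, 1L], logits[, 2L])
  e1 <- exp(logits[, 1L] - m); e2 <- exp(logits[, 2L] - m)
  cbind(e1, e2) / (e1 + e2)
}

#' Fit a supervised autoencoder
#'
#' @param X Samples x features matrix on the standardised log scale (see
#'   [normalize_intensities()]).
#' @param y Two-class labels; `"malignant"` is the positive class.
#' @param config An [sae_config()].
#' @return An `sae_model`.
#' @export
fit_sae <- function(X, y, config = sae_config()) {
  stopifnot(inherits(config, "sae_config"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  cc <- code_classes(y)
  n <- nrow(X); p <- ncol(X)
  tab <- table(factor(as.character(y), levels = cc$classes))
  if (any(tab < 4))
    abort_validation("each class needs at least 4 samples to fit the SAE")
  cw <- config$class_weights %||%
    stats::setNames(n / (2 * as.numeric(tab)), cc$classes)
  if (!all(cc$classes %in% names(cw)))
    abort_validation("class_weights must be named with both class labels")
  w <- as.numeric(cw[as.character(y)])
  y_idx <- ifelse(as.character(y) == cc$classes[2L], 2L, 1L)

  dims_enc <- c(p, config$hidden_sizes, config$latent_dim)
  dims_dec <- c(config$latent_dim, rev(config$hidden_sizes), p)
  lambda <- config$recon_weight
  lr <- config$learning_rate

  with_seed(config$seed, {
    enc <- mapply(init_layer, dims_enc[-length(dims_enc)], dims_enc[-1L],
                  SIMPLIFY = FALSE)
    dec <- mapply(init_layer, dims_dec[-length(dims_dec)], dims_dec[-1L],
                  SIMPLIFY = FALSE)
    clf <- list(init_layer(config$latent_dim, 2L))
    st_enc <- adam_init(enc); st_dec <- adam_init(dec)
    st_clf <- adam_init(clf)
    trace <- numeric(config$epochs)
    t_step <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        nb <- length(bi)
        Xb <- X[bi, , drop = FALSE]
        fe <- stack_forward(Xb, enc)
        L <- fe$out
        fc <- stack_forward(L, clf)
        fd <- stack_forward(L, dec)
        prob <- softmax2(fc$out)
        wb <- w[bi]; sw <- sum(wb)
        picked <- prob[cbind(seq_len(nb), y_idx[bi])]
        loss_cls <- sum(wb * -log(pmax(picked, 1e-12))) / sw
        resid <- fd$out - Xb
        loss_rec <- mean(resid^2)
        loss <- loss_cls + lambda * loss_rec
        if (!is.finite(loss))
          stop(errorCondition(
            sprintf("non-finite SAE loss at epoch %d", epoch),
            class = c("fnacmet_training_error", "fnacmet_error")))
        ep_loss <- ep_loss + loss * nb

        onehot <- matrix(0, nb, 2L)
        onehot[cbind(seq_len(nb), y_idx[bi])] <- 1
        dlogits <- (prob - onehot) * wb / sw
        bc <- stack_backward(L, clf, fc, dlogits)
        dXhat <- 2 * lambda * resid / (nb * p)
        bd <- stack_backward(L, dec, fd, dXhat)
        G_latent <- bc$G_input + bd$G_input
        be <- stack_backward(Xb, enc, fe, G_latent)

        t_step <- t_step + 1L
        up <- adam_step(enc, be$grads, st_enc, lr, t_step)
        enc <- up$layers; st_enc <- up$state
        up <- adam_step(dec, bd$grads, st_dec, lr, t_step)
        dec <- up$layers; st_dec <- up$state
        up <- adam_step(clf, bc$grads, st_clf, lr, t_step)
        clf <- up$layers; st_clf <- up$state
      }
      trace[epoch] <- ep_loss / n
    }
    structure(list(encoder = enc, decoder = dec, classifier = clf,
                   config = config, classes = cc$classes,
                   class_weights = cw,
                   feature_names = colnames(X),
                   loss_trace = trace),
              class = "sae_model")
  })
}

#' @export
print.sae_model <- function(x, ...) {
  cat(sprintf(
    "<sae_model> %d features -> [%s] -> %d latent; final loss %.4f\n",
    length(x$feature_names),
    paste(x$config$hidden_sizes, collapse = ","),
    x$config$latent_dim, x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

check_sae_input <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$feature_names))
    abort_validation("X has %d features but the model expects %d",
                     ncol(X), length(model$feature_names))
  if (!is.null(colnames(X))) {
    if (!setequal(colnames(X), model$feature_names))
      abort_validation("X column names do not match the model's features")
    X <- X[, model$feature_names, drop = FALSE]
  }
  X
}

#' Latent-space coordinates of samples
#' @param model A fitted `sae_model`.
#' @param X Samples x features matrix.
#' @return Matrix of latent coordinates (n x latent_dim).
#' @export
project_latent <- function(model, X) {
  stopifnot(inherits(model, "sae_model"))
  X <- check_sae_input(model, X)
  stack_forward(X, model$encoder)$out
}

#' Predicted malignant probability
#' @inheritParams project_latent
#' @return Numeric vector in `[0, 1]`, one value per sample.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "sae_model"))
  L <- project_latent(model, X)
  softmax2(stack_forward(L, model$classifier)$out)[, 2L]
}

#' Predicted class labels at probability threshold 0.5
#'
#' An exact 0.5 resolves to the benign class.
#' @inheritParams project_latent
#' @return Character vector of class labels.
#' @export
predict_sae <- function(model, X) {
  pr <- predict_proba(model, X)
  ifelse(pr > 0.5, model$classes[2L], model$classes[1L])
}

#' Signed per-feature importance scores
#'
#' The score of feature `j` is the mean, over the given samples, of the
#' input gradient of the logit difference (malignant minus benign).
#' Positive scores push predictions towards malignant; the sign is
#' retained. The definition is architecture-agnostic: a feature ignored
#' by the encoder scores exactly 0, and duplicated inputs entering with
#' identical weights score identically.
#'
#' @inheritParams project_latent
#' @return Named numeric vector, one score per feature.
#' @export
feature_scores <- function(model, X) {
  stopifnot(inherits(model, "sae_model"))
  X <- check_sae_input(model, X)
  fe <- stack_forward(X, model$encoder)
  v <- model$classifier[[1L]]$W[, 2L] - model$classifier[[1L]]$W[, 1L]
  G <- matrix(v, nrow(X), length(v), byrow = TRUE)
  b <- stack_backward(X, model$encoder, fe, G)
  stats::setNames(colMeans(b$G_input), model$feature_names)
}

silverman_bw <- function(x) {
  s <- stats::sd(x)
  iq <- stats::IQR(x) / 1.349
  lo <- min(s, iq)
  if (!is.finite(lo) || lo <= 0) lo <- 0
  max(0.9 * lo * length(x)^(-1 / 5), 1e-3)
}

# Gaussian KDE reflected at 0 and 1, so probability mass stays in [0, 1]
reflected_kde <- function(data, at, bw) {
  k <- function(centers) {
    sapply(at, function(x) mean(stats::dnorm(x, centers, bw)))
  }
  k(data) + k(-data) + k(2 - data)
}

#' Class-conditional density of the prediction probability
#'
#' Kernel density estimates (Gaussian, Silverman bandwidth per class,
#' reflected at the 0/1 boundaries) of the predicted malignant
#' probability within each true class, plus a per-sample confidence
#' score: the density of the sample's own class at its probability,
#' relative to the sum of both class densities there.
#'
#' @param probs Predicted malignant probabilities.
#' @param y True class labels (two classes, each with >= 2 samples).
#' @param grid_n Number of grid points on `[0, 1]` (default 512).
#' @return A `confidence_curves` list with `grid`, `density_benign`,
#'   `density_malignant`, `confidence`, `bandwidths`.
#' @export
confidence_curves <- function(probs, y, grid_n = 512) {
  cc <- code_classes(y)
  ben <- probs[cc$coded < 0]; mal <- probs[cc$coded > 0]
  if (length(ben) < 2 || length(mal) < 2)
    abort_validation("each class needs at least 2 samples")
  bw_b <- silverman_bw(ben); bw_m <- silverman_bw(mal)
  grid <- seq(0, 1, length.out = grid_n)
  d_b <- reflected_kde(ben, grid, bw_b)
  d_m <- reflected_kde(mal, grid, bw_m)
  own_b <- reflected_kde(ben, probs, bw_b)
  own_m <- reflected_kde(mal, probs, bw_m)
  d_own <- ifelse(cc$coded < 0, own_b, own_m)
  d_oth <- ifelse(cc$coded < 0, own_m, own_b)
  conf <- ifelse(d_own + d_oth > 0, d_own / (d_own + d_oth), 0.5)
  structure(list(grid = grid, density_benign = d_b, density_malignant = d_m,
                 confidence = conf, bandwidths = c(benign = bw_b,
                                                   malignant = bw_m)),
            class = "confidence_curves")
}

#' Benign-over-malignant mean intensity ratio
#'
#' Effect-size summary of one feature on the raw intensity scale: the
#' mean intensity over benign sample runs divided by the mean over
#' malignant sample runs.
#'
#' @param table A [feature_table] with labelled sample runs.
#' @param feature_id Feature identifier.
#' @return Positive real; `Inf` (with a warning) when the malignant mean
#'   is zero.
#' @export
bm_ratio <- function(table, feature_id) {
  stopifnot(inherits(table, "feature_table"))
  i <- match(feature_id, table$features$feature_id)
  if (is.na(i)) abort_validation("unknown feature '%s'", feature_id)
  is_sample <- table$samples$role == "sample"
  ben <- is_sample & table$samples$class_label == "benign"
  mal <- is_sample & table$samples$class_label == "malignant"
  if (!any(ben) || !any(mal))
    abort_validation("both classes must be present")
  mb <- mean(table$intensities[i, ben])
  mm <- mean(table$intensities[i, mal])
  if (mm == 0) {
    warning(sprintf("feature '%s': malignant mean is zero", feature_id))
    return(Inf)
  }
  mb / mm
}

#' Step-by-step top-down signature selection
#'
#' Iteratively fits the SAE, ranks features by absolute importance score
#' and keeps the top `ceiling((1 - drop_fraction) * p)` (never fewer than
#' `k`), until exactly `k` features remain; a final model is refitted on
#' those `k`. Each round uses a seed derived deterministically from the
#' configured seed.
#'
#' Within each elimination round the ranking score is the absolute input
#' gradient averaged over `n_scoring_fits` replicate fits trained with a
#' conservative learning rate (`scoring_config`): gently-trained replicas
#' give importance rankings dominated by the reproducible class signal
#' rather than by run-specific noise fitting, which stabilises the
#' selection considerably, while the final refit on the `k` survivors
#' uses the full `config` so the returned model is trained to
#' convergence.
#'
#' @param X Samples x features matrix (standardised log scale) with
#'   feature ids as column names.
#' @param y Two-class labels.
#' @param k Signature size (default 15).
#' @param drop_fraction Fraction of features dropped per round, in (0, 1)
#'   (default 0.5).
#' @param config An [sae_config()] used for the final refit.
#' @param n_scoring_fits Replicate fits averaged per elimination round
#'   (default 3).
#' @param scoring_config [sae_config()] for the scoring replicas;
#'   defaults to `config` with the learning rate lowered to 1e-3.
#' @param table Optional raw-intensity [feature_table] used to attach
#'   benign/malignant ratios and consensus m/z and RT to the signature.
#' @param annotations,compounds Optional annotation results used to
#'   attach a main identity per signature ion.
#' @return An `sae_signature`: list with `entries` (data frame ordered by
#'   descending score), `model` (the final refit) and `history` (feature
#'   counts per round).
#' @export
topdown_select <- function(X, y, k = 15, drop_fraction = 0.5,
                           config = sae_config(), n_scoring_fits = 3,
                           scoring_config = NULL, table = NULL,
                           annotations = NULL, compounds = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  if (k >= ncol(X))
    abort_validation("k (%d) must be smaller than the feature count (%d)",
                     k, ncol(X))
  if (!is.numeric(drop_fraction) || drop_fraction <= 0 || drop_fraction >= 1)
    abort_validation("`drop_fraction` must lie strictly between 0 and 1")
  if (is.null(scoring_config)) {
    scoring_config <- config
    scoring_config$learning_rate <- min(config$learning_rate, 1e-3)
  }
  if (n_scoring_fits < 1)
    abort_validation("`n_scoring_fits` must be at least 1")
  cur <- X
  history <- ncol(X)
  round <- 0L
  while (ncol(cur) > k) {
    round <- round + 1L
    sc <- 0
    for (j in seq_len(n_scoring_fits)) {
      cfg <- scoring_config
      cfg$seed <- derive_seed(config$seed, round * 100L + j)
      m <- fit_sae(cur, y, cfg)
      sc <- sc + abs(feature_scores(m, cur))
    }
    keep_n <- max(k, ceiling((1 - drop_fraction) * ncol(cur)))
    keep_n <- min(keep_n, ncol(cur) - 1L)
    keep <- sort(order(-sc)[seq_len(keep_n)])
    cur <- cur[, keep, drop = FALSE]
    history <- c(history, ncol(cur))
  }
  final <- fit_sae(cur, y, config)
  sc <- feature_scores(final, cur)
  ids <- colnames(cur)
  entries <- data.frame(feature_id = ids, sae_score = as.numeric(sc),
                        stringsAsFactors = FALSE)
  if (!is.null(table)) {
    fi <- match(ids, table$features$feature_id)
    entries$ion_mode <- table$features$mode[fi]
    entries$mz <- table$features$mz[fi]
    entries$rt_min <- table$features$rt[fi]
    entries$bm_ratio <- vapply(ids, function(f) bm_ratio(table, f),
                               numeric(1))
  } else {
    entries$bm_ratio <- NA_real_
  }
  entries$main_identity <- ""
  entries$hmdb_id <- ""
  entries$formula <- ""
  if (!is.null(annotations) && nrow(annotations) && !is.null(compounds)) {
    for (i in seq_along(ids)) {
      ann <- annotations[annotations$feature_id == ids[i], , drop = FALSE]
      if (nrow(ann)) {
        cmp <- compounds[match(ann$compound_id[1L], compounds$compound_id), ]
        entries$main_identity[i] <- cmp$name %||% ""
        entries$hmdb_id[i] <- cmp$compound_id
        entries$formula[i] <- cmp$formula %||% ""
      }
    }
  }
  entries <- entries[order(-entries$sae_score), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries, model = final, history = history,
                 k = k), class = "sae_signature")
}

#' @export
print.sae_signature <- function(x, ...) {
  cat(sprintf("<sae_signature> %d ions (elimination path: %s)\n",
              x$k, paste(x$history, collapse = " -> ")))
  print(utils::head(x$entries[, c("feature_id", "sae_score", "bm_ratio")],
                    x$k))
  invisible(x)
}

#' Write a signature as a signature-table CSV and JSON
#' @param signature An `sae_signature`.
#' @param path Output CSV path; a JSON twin is written next to it.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "sae_signature"))
  cols <- c("ion_mode", "mz", "rt_min", "main_identity", "hmdb_id",
            "formula", "sae_score", "bm_ratio")
  df <- signature$entries
  for (cn in cols) if (is.null(df[[cn]])) df[[cn]] <- NA
  utils::write.csv(df[, c("feature_id", cols)], path, row.names = FALSE)
  jsonlite::write_json(df, sub("\\.csv$", ".json", path),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
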