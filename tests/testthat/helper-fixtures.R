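# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

get_fixture <- function() cached("fixture_cohort", fixture_cohort())

# the fixture's normalised model matrix (samples x features) and labels
get_fixture_model_data <- function() cached("fixture_model", {
  fx <- get_fixture()
  norm <- normalize_intensities(fx$truth_table)
  list(X = t(norm$values), y = norm$class_labels,
       informative = fx$informative_ids, norm = norm,
       table = fx$truth_table)
})

# small labelled feature table built by hand: intensities chosen so every
# filter decision is knowable at a glance
make_toy_table <- function(intensities, roles = NULL, labels = NULL) {
  n_feat <- nrow(intensities)
  n_run <- ncol(intensities)
  if (is.null(roles)) roles <- rep("sample", n_run)
  if (is.null(labels))
    labels <- ifelse(roles == "sample", "benign", "none")
  feature_table(
    data.frame(feature_id = sprintf("F%03d", seq_len(n_feat)),
               mode = rep("positive", n_feat),
               mz = 100 + seq_len(n_feat), rt = seq_len(n_feat) %% 20 + 1,
               evidence_flag = rep(TRUE, n_feat)),
    data.frame(run_id = sprintf("R%02d", seq_len(n_run)), role = roles,
               class_label = labels),
    intensities)
}

# two well-separated gaussian classes; linearly separable when sd is small
make_separable_toy <- function(n_per_class = 10, p = 2, sd = 0.1,
                               seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p, -3, sd), n_per_class, p),
             matrix(rnorm(n_per_class * p, 3, sd), n_per_class, p))
  colnames(X) <- sprintf("f%02d", seq_len(p))
  list(X = X, y = rep(c("benign", "malignant"), each = n_per_class))
}

# single-linkage clustering oracle for alignment: peaks are linked when
# both tolerances hold (ppm relative to the lighter peak), and features
# are the connected components
single_linkage_features <- function(peaks, mz_tol_ppm, rt_tol_min) {
  n <- nrow(peaks)
  if (n == 0) return(integer(0))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ppm <- abs(peaks$mz[i] - peaks$mz[j]) /
      min(peaks$mz[i], peaks$mz[j]) * 1e6
    if (ppm <= mz_tol_ppm && abs(peaks$rt[i] - peaks$rt[j]) <= rt_tol_min)
      adj[i, j] <- adj[j, i] <- TRUE
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# trapezoidal ROC integration oracle for the AUC equivalence check
trapezoid_auc <- function(y_true, scores, positive = "malignant") {
  pos <- as.character(y_true) == positive
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[pos] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(th, function(t) mean(scores[!pos] >= t), numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# hand-built SAE model with fully controlled weights (for score checks)
manual_sae <- function(W1, b1, W2, b2, Wc, bc) {
  structure(list(
    encoder = list(list(W = W1, b = b1), list(W = W2, b = b2)),
    decoder = list(list(W = t(W2), b = rep(0, ncol(W1))),
                   list(W = t(W1), b = rep(0, nrow(W1)))),
    classifier = list(list(W = Wc, b = bc)),
    config = sae_config(hidden_sizes = ncol(W1), latent_dim = ncol(W2)),
    classes = c("benign", "malignant"),
    class_weights = c(benign = 1, malignant = 1),
    feature_names = sprintf("f%02d", seq_len(nrow(W1))),
    loss_trace = numeric(0)), class = "sae_model")
}
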