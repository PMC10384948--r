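# Internal helpers: classed conditions and small validators.

abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fnacmet_validation_error", "fnacmet_error")))
}

abort_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fnacmet_format_error", "fnacmet_error")))
}

abort_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fnacmet_domain_error", "fnacmet_error")))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation("`%s` must be a single finite number", name)
  if (positive && x <= 0)
    abort_validation("`%s` must be positive", name)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run a block with a private RNG stream so callers' .Random.seed survives.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic fan-out of a global seed into per-stage streams (< 2^31).
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 10007) %% 2147483647)
}
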