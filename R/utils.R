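## Internal helpers: argument checking and seeded, side-effect-free RNG.

stop_domain <- function(...) stop(..., call. = FALSE)

check_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    stop_domain(sprintf("`%s` must be positive", name))
  if (nonneg && x < 0)
    stop_domain(sprintf("`%s` must be non-negative", name))
  as.numeric(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_domain(sprintf("`%s` must be an integer >= %d", name, min))
  as.integer(x)
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state. All stochastic operations in the package funnel through this,
## which is what makes simulate_trial() / train_cnn() pure functions of
## their seed arguments.
with_seed <- function(seed, expr) {
  seed <- check_count(seed, "seed", min = 0L)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic integer hash used to give every (subject, gesture, trial)
#' or (subject, configuration) cell of an experiment its own RNG stream
#' derived from one master seed. The hash is a multiplicative congruential
#' mix reduced modulo 2^31 - 1, so derived seeds always fit in a 32-bit
#' integer.
#'
#' @param master_seed Integer master seed.
#' @param ... Further non-negative integer indices identifying the cell.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, ...) {
  master_seed <- check_count(master_seed, "master_seed", min = 0L)
  idx <- c(...)
  h <- as.numeric(master_seed) %% 2147483647
  for (k in idx) {
    k <- check_count(k, "index", min = 0L)
    h <- (h * 48271 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(h)
}
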