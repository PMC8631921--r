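# Independent oracles used across the suite. These deliberately avoid the
# package's fast code paths: the CWT oracle evaluates the transform
# integral as an explicit Riemann sum, the spectrogram oracle as explicit
# DFT sums, and the counting oracles as plain loops.

# Riemann-sum CWT: X[s, a] = sum_i x_i psi((i - a)/b_s) / sqrt(b_s),
# evaluated scale by scale with an explicit translation-difference matrix.
direct_cwt <- function(x, spec, grid) {
  n <- length(x)
  out <- matrix(0 + 0i, grid$n_scales, n)
  idx <- seq_len(n)
  for (s in seq_len(grid$n_scales)) {
    b <- grid$scales[s]
    U <- outer(idx, idx, function(i, a) (i - a) / b)   # n x n argument grid
    P <- matrix(mother_wavelet(spec, as.numeric(U)), n, n)
    out[s, ] <- as.vector(x %*% P) / sqrt(b)
  }
  out
}

# Explicit DFT of one frame: F[k] = sum_j v_j exp(-2 pi i (j-1)(k-1)/m)
direct_dft <- function(v) {
  m <- length(v)
  vapply(seq_len(m), function(k) {
    sum(v * exp(-2i * pi * (seq_len(m) - 1) * (k - 1) / m))
  }, complex(1))
}

# Loop-counting accuracy oracle
count_matches <- function(truth, pred) {
  hits <- 0L
  for (i in seq_along(truth)) if (truth[i] == pred[i]) hits <- hits + 1L
  hits / length(truth)
}

# Nested-loop confusion tally
tally_confusion <- function(truth, pred, vocab) {
  m <- matrix(0L, length(vocab), length(vocab),
              dimnames = list(true = vocab, predicted = vocab))
  for (i in seq_along(truth)) {
    r <- which(vocab == truth[i]); c <- which(vocab == pred[i])
    m[r, c] <- m[r, c] + 1L
  }
  m
}

# Sliding-window count by explicit offset enumeration
enumerate_offsets <- function(n, w, s) {
  offs <- integer(0)
  o <- 0L
  while (o + w <= n) {
    offs <- c(offs, o)
    o <- o + s
  }
  offs
}

# Term-by-term evaluation of the conditioning-circuit gain formula,
# written independently of theoretical_gain()
gain_by_terms <- function(R_G, R_2, R_3, R_c1, R_c2, R_c3) {
  t1 <- if (is.finite(R_G)) 49.4e3 / R_G else 0
  first <- t1 + R_c1 + 1
  num <- R_3 * R_c3
  den <- R_c2 * R_c3 + R_2 * R_c2 + R_2 * R_c3 + R_2 * R_3
  first * num / den
}

# Small synthetic separable feature set for classifier tests
tiny_feature_set <- function(n_per_class = 20L, classes = c("A", "B"),
                             h = 8L, w = 12L, ch = 6L, seed = 9L) {
  n <- n_per_class * length(classes)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x <- array(rnorm(h * w * ch * n, sd = 0.3), c(h, w, ch, n))
  lab <- rep(classes, each = n_per_class)
  for (k in seq_along(classes))
    x[, , k, lab == classes[k]] <- x[, , k, lab == classes[k]] + 2
  list(x = x, labels = lab)
}
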