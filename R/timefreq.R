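## timefreq: mother-wavelet families, admissibility, the continuous wavelet
## transform and the scalogram stacks that feed the classifier.

WAVELET_FAMILIES <- c("mexh", "gaus", "cmor", "shan", "fbsp", "cgau")

## Unnormalized family formulas. `t` in the mother wavelet's natural time
## unit. The printed normalization constants for mexh/gaus/cgau are
## typographically unreliable in the source tables this package follows,
## so constants are resolved by unit-energy quadrature at construction.
wavelet_raw <- function(family, t, f_b, f_c, m) {
  sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  switch(family,
    mexh = (1 - t^2) * exp(-t^2 / 2),
    gaus = t * exp(-t^2),
    cmor = (1 / sqrt(pi * f_b)) * exp(2i * pi * f_c * t - t^2 / f_b),
    shan = sqrt(f_b) * sinc(f_b * t) * exp(2i * pi * f_c * t),
    fbsp = sqrt(f_b) * sinc(f_b * t / m)^m * exp(2i * pi * f_c * t),
    ## first-order complex Gaussian: d/dt [exp(-it) exp(-t^2)]. The
    ## undifferentiated product form sometimes quoted for this family has
    ## a non-zero mean and is not admissible; the derivative is.
    cgau = (-1i - 2 * t) * exp(-1i * t) * exp(-t^2),
    stop_domain("unknown wavelet family: ", family))
}

#' Mother-wavelet specification
#'
#' Parametrizes one of six mother-wavelet families: Mexican hat (`mexh`),
#' first-order Gaussian derivative (`gaus`), complex Morlet (`cmor`),
#' Shannon (`shan`), frequency B-spline (`fbsp`) and first-order complex
#' Gaussian (`cgau`). `cmor`/`shan`/`fbsp` take a bandwidth parameter
#' `f_b` and centre frequency `f_c`; `fbsp` additionally an integer order
#' `m`. Normalization constants for `mexh`, `gaus` and `cgau` are fixed
#' by unit-energy quadrature at construction; the centre frequency of the
#' sampled wavelet (`f_c_eff`, used for the scale/pseudo-frequency map)
#' is located numerically from the peak of its Fourier magnitude.
#'
#' @param family One of `"mexh"`, `"gaus"`, `"cmor"`, `"shan"`, `"fbsp"`,
#'   `"cgau"` (case-insensitive).
#' @param f_b Bandwidth parameter (`cmor`/`shan`/`fbsp`), positive.
#' @param f_c Centre frequency (`cmor`/`shan`/`fbsp`), positive.
#' @param m Frequency B-spline order (`fbsp`), positive integer.
#' @return An object of class `wavelet_spec` with fields `family`, `f_b`,
#'   `f_c`, `m`, `norm_const`, `f_c_eff`, `is_complex`.
#' @export
wavelet_spec <- function(family, f_b = 1.5, f_c = 1.0, m = 2L) {
  family <- tolower(as.character(family))
  if (length(family) != 1L || !(family %in% WAVELET_FAMILIES))
    stop_domain("`family` must be one of: ", paste(WAVELET_FAMILIES, collapse = ", "))
  needs_fbfc <- family %in% c("cmor", "shan", "fbsp")
  if (needs_fbfc) {
    f_b <- check_scalar_num(f_b, "f_b", positive = TRUE)
    f_c <- check_scalar_num(f_c, "f_c", positive = TRUE)
  }
  if (family == "fbsp") m <- check_count(m, "m", min = 1L)

  ## unit-energy constant by quadrature (identity for printed-normalized families)
  dt <- 1 / 64
  tq <- seq(-40, 40, by = dt)
  raw <- wavelet_raw(family, tq, f_b, f_c, m)
  norm_const <- if (family %in% c("mexh", "gaus", "cgau")) {
    1 / sqrt(sum(Mod(raw)^2) * dt)
  } else 1

  spec <- structure(list(family = family, f_b = f_b, f_c = f_c, m = m,
                         norm_const = norm_const,
                         is_complex = family %in% c("cmor", "shan", "fbsp", "cgau")),
                    class = "wavelet_spec")
  spec$f_c_eff <- wavelet_center_frequency(spec)
  spec
}

#' @export
print.wavelet_spec <- function(x, ...) {
  extra <- if (x$family %in% c("cmor", "shan", "fbsp"))
    sprintf(" f_b=%g f_c=%g%s", x$f_b, x$f_c,
            if (x$family == "fbsp") sprintf(" m=%d", x$m) else "") else ""
  cat(sprintf("<wavelet_spec> %s%s (f_c_eff=%.4f, %s)\n", toupper(x$family),
              extra, x$f_c_eff, if (x$is_complex) "complex" else "real"))
  invisible(x)
}

#' Evaluate a mother wavelet on a time grid
#'
#' @param spec A [wavelet_spec()].
#' @param t_grid Numeric vector of evaluation times (mother-wavelet time
#'   units), typically symmetric about 0.
#' @return Numeric vector for the real families (`mexh`, `gaus`), complex
#'   vector otherwise.
#' @export
mother_wavelet <- function(spec, t_grid) {
  if (!inherits(spec, "wavelet_spec"))
    stop_domain("`spec` must be a wavelet_spec object")
  out <- spec$norm_const * wavelet_raw(spec$family, t_grid, spec$f_b, spec$f_c, spec$m)
  if (!spec$is_complex) Re(out) else out
}

## Numerically locate the frequency at which |FT(psi)| peaks, with
## quadratic interpolation of the discrete peak.
wavelet_center_frequency <- function(spec) {
  dt <- 1 / 32
  tq <- seq(-64, 64 - dt, by = dt)
  psi <- mother_wavelet(spec, tq)
  n <- length(psi)
  pad <- 2^17
  ph <- fft(c(psi, rep(0, pad - n)))
  freqs <- (seq_len(pad) - 1) / (pad * dt)
  freqs[freqs > 1 / (2 * dt)] <- freqs[freqs > 1 / (2 * dt)] - 1 / dt
  ## search both spectral halves (a modulated wavelet may be centred at a
  ## negative frequency); the pseudo-frequency map uses the magnitude.
  half <- which(freqs != 0)
  mag <- Mod(ph[half])
  i <- which.max(mag)
  ## quadratic peak interpolation
  if (i > 1 && i < length(mag)) {
    y1 <- mag[i - 1]; y2 <- mag[i]; y3 <- mag[i + 1]
    denom <- y1 - 2 * y2 + y3
    delta <- if (denom != 0) 0.5 * (y1 - y3) / denom else 0
  } else delta <- 0
  abs(freqs[half[i]] + delta * (freqs[2] - freqs[1]))
}

#' Admissibility check for a wavelet
#'
#' Numerically verifies the admissibility condition: finiteness of
#' \eqn{\int |\hat\psi(\omega)|^2 / \omega \, d\omega}, which requires
#' the wavelet to have zero mean. Two diagnostics are computed on a long
#' sampled grid: the admissibility integral over the sampled spectrum,
#' and the mean residual \eqn{|\int \psi\,dt|} relative to the L1 norm.
#' For slowly decaying envelopes (Shannon's sinc tail) the mean is
#' computed by tail-averaging the cumulative trapezoid integral over the
#' last beat periods, which cancels the oscillatory truncation error.
#' A candidate passes when the relative mean residual is below `tol` and
#' the integral is finite.
#'
#' @param spec A [wavelet_spec()], or an arbitrary function `f(t)` to
#'   check as a candidate wavelet (e.g. a non-admissible control bump).
#' @param tol Relative zero-mean tolerance (default `1e-6`).
#' @return List with `pass` (logical), `cv_integral`, `mean_residual`
#'   (absolute), `l1_norm` and `relative_residual`.
#' @export
admissibility_check <- function(spec, tol = 1e-6) {
  f <- if (inherits(spec, "wavelet_spec")) {
    function(t) mother_wavelet(spec, t)
  } else if (is.function(spec)) spec
  else stop_domain("`spec` must be a wavelet_spec or a function of t")

  dt <- 1 / 64
  T_max <- 400
  tq <- seq(-T_max, T_max, by = dt)
  psi <- f(tq)
  l1 <- sum(Mod(psi)) * dt

  ## symmetric partial integrals I(T') via outward cumulative trapezoid
  n <- length(tq)
  mid <- (n + 1L) %/% 2L                       # t = 0
  k <- seq_len(mid - 1L)
  pair <- psi[mid + k] + psi[mid - k]
  ## I(T_k) = dt * (psi(0) + sum_{j<=k} pair_j - pair_k / 2), trapezoid rule
  partial <- dt * (psi[mid] + cumsum(pair) - pair / 2)
  ## tail-average over the last 8 time units (integer beat periods)
  n_avg <- round(8 / dt)
  residual <- Mod(mean(tail(partial, n_avg)))

  ## admissibility integral over the sampled positive spectrum
  ph <- fft(psi) * dt
  freqs <- (seq_len(n) - 1) / (n * dt)
  pos <- freqs > 0 & freqs <= 1 / (2 * dt)
  omega <- 2 * pi * freqs[pos]
  cv <- sum(Mod(ph[pos])^2 / omega) * (omega[2] - omega[1])

  rel <- residual / l1
  list(pass = is.finite(cv) && rel < tol,
       cv_integral = cv, mean_residual = residual,
       l1_norm = l1, relative_residual = rel)
}

#' Build the scale grid for the CWT
#'
#' Maps `n_scales` logarithmically spaced pseudo-frequencies between
#' `f_min_hz` and `f_max_hz` to wavelet scales via
#' `scale = f_c_eff * fs / f_pseudo` (scale in samples). Pseudo-
#' frequencies are stored in decreasing order, so scales increase along
#' the grid and the first scalogram row is the highest frequency.
#'
#' @param n_scales Number of scales (default 64).
#' @param spec A [wavelet_spec()]; its `f_c_eff` sets the map.
#' @param sampling_rate_hz Sampling rate of the analyzed signal, Hz.
#' @param f_min_hz,f_max_hz Pseudo-frequency endpoints, Hz;
#'   `f_max_hz` must not exceed Nyquist.
#' @return An object of class `scale_grid` with fields `scales`,
#'   `pseudo_freqs_hz`, `sampling_rate_hz`, `n_scales`.
#' @export
make_scale_grid <- function(n_scales = 64L, spec = wavelet_spec("mexh"),
                            sampling_rate_hz = 2000, f_min_hz = 5, f_max_hz = 1000) {
  n_scales <- check_count(n_scales, "n_scales", min = 2L)
  sampling_rate_hz <- check_scalar_num(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  f_min_hz <- check_scalar_num(f_min_hz, "f_min_hz", positive = TRUE)
  f_max_hz <- check_scalar_num(f_max_hz, "f_max_hz", positive = TRUE)
  if (f_min_hz >= f_max_hz) stop_domain("f_min_hz must be < f_max_hz")
  if (f_max_hz > sampling_rate_hz / 2)
    stop_domain("f_max_hz must not exceed the Nyquist frequency")
  if (!inherits(spec, "wavelet_spec"))
    stop_domain("`spec` must be a wavelet_spec object")
  f_p <- exp(seq(log(f_max_hz), log(f_min_hz), length.out = n_scales))
  structure(list(scales = spec$f_c_eff * sampling_rate_hz / f_p,
                 pseudo_freqs_hz = f_p,
                 sampling_rate_hz = sampling_rate_hz,
                 n_scales = n_scales),
            class = "scale_grid")
}

#' Precompute FFT convolution kernels for the CWT
#'
#' The CWT of a length-`n` signal is a bank of correlations with dilated
#' wavelets. This precomputes the frequency-domain kernels for every
#' scale so repeated transforms of same-length signals (scalogram
#' batches) reuse them.
#'
#' @param spec A [wavelet_spec()].
#' @param grid A [make_scale_grid()] object.
#' @param n Signal length in samples.
#' @return Opaque kernel object consumed by [cwt()].
#' @export
make_cwt_kernels <- function(spec, grid, n) {
  n <- check_count(n, "n")
  j <- -(n - 1):(n - 1)                        # kernel support, samples
  L <- nextn(3L * n - 2L, 2L)
  K <- matrix(0 + 0i, L, grid$n_scales)
  for (s in seq_len(grid$n_scales)) {
    b <- grid$scales[s]
    kv <- mother_wavelet(spec, j / b) / sqrt(b)
    K[, s] <- fft(c(rev(kv), rep(0, L - length(kv))))
  }
  structure(list(K = K, n = n, L = L, n_scales = grid$n_scales,
                 family = spec$family), class = "cwt_kernels")
}

#' Continuous wavelet transform of one channel
#'
#' Discretizes \eqn{X(a,b) = b^{-1/2} \int x(t)\,\psi((t-a)/b)\,dt} on
#' the signal's sample grid (unit sample spacing, one translation per
#' sample, zero extension beyond the signal) and evaluates it for every
#' scale of the grid by FFT convolution.
#'
#' @param segment_channel Numeric vector, one channel of a window.
#' @param spec A [wavelet_spec()].
#' @param grid A [make_scale_grid()] object.
#' @param kernels Optional precomputed [make_cwt_kernels()] for
#'   `length(segment_channel)`.
#' @return Complex matrix, `n_scales x n_times` (real families produce a
#'   complex matrix with zero imaginary part).
#' @export
cwt <- function(segment_channel, spec, grid, kernels = NULL) {
  x <- as.numeric(segment_channel)
  n <- length(x)
  if (n < 1) stop_domain("empty signal")
  if (is.null(kernels)) kernels <- make_cwt_kernels(spec, grid, n)
  if (!inherits(kernels, "cwt_kernels") || kernels$n != n)
    stop_domain("`kernels` do not match the signal length")
  L <- kernels$L
  xf <- fft(c(x, rep(0, L - n)))
  Z <- mvfft(kernels$K * xf, inverse = TRUE) / L
  ## full convolution index q = a + n - 1 for translations a = 1..n
  t(Z[n:(2 * n - 1), , drop = FALSE])
}

#' STFT spectrogram of one channel
#'
#' Squared magnitude of the windowed short-time Fourier transform:
#' frames of `length(window_fn)` samples taken every `hop` samples, each
#' multiplied by `window_fn` and Fourier transformed. Provided as the
#' classical fixed-resolution alternative to the CWT scalogram.
#'
#' @param segment_channel Numeric vector.
#' @param window_fn Numeric analysis window (its length sets the frame).
#' @param hop Frame advance in samples.
#' @return Non-negative matrix, frequency bins x frames, with attribute
#'   `"freq_bins"` giving the DFT bin index (0-based).
#' @export
stft_spectrogram <- function(segment_channel, window_fn, hop = length(window_fn)) {
  x <- as.numeric(segment_channel)
  wl <- length(window_fn)
  hop <- check_count(hop, "hop")
  if (wl > length(x)) stop_domain("window longer than signal")
  starts <- seq(1L, length(x) - wl + 1L, by = hop)
  frames <- vapply(starts, function(s) x[s:(s + wl - 1L)] * window_fn, numeric(wl))
  S <- Mod(mvfft(frames))^2
  structure(S, freq_bins = 0:(wl - 1L))
}

#' Scalogram feature tensor for one window
#'
#' Per channel, the CWT magnitude over the scale grid, stacked into a
#' `(n_channels, n_scales, n_times)` array — `(6, 64, 264)` under the
#' defaults — the classifier's input. Optionally applies a per-channel
#' standardization whose statistics (typically fit on the training set
#' with [fit_feature_normalization()]) are kept on the result so the
#' transform is invertible.
#'
#' @param window A `window_segment` from [sliding_windows()].
#' @param spec A [wavelet_spec()].
#' @param grid A [make_scale_grid()] object.
#' @param normalization `NULL` (raw magnitudes) or a list
#'   `list(scheme = "per_channel_zscore", mean =, sd =)` with one value
#'   per channel.
#' @param kernels Optional precomputed [make_cwt_kernels()].
#' @param squared Logical; use squared magnitude instead of plain
#'   magnitude (default `FALSE`).
#' @return 3-D array with attributes `normalization` and `provenance`.
#' @export
scalogram_stack <- function(window, spec, grid, normalization = NULL,
                            kernels = NULL, squared = FALSE) {
  if (!inherits(window, "window_segment"))
    stop_domain("`window` must be a window_segment object")
  n_ch <- nrow(window$samples)
  n <- ncol(window$samples)
  if (is.null(kernels)) kernels <- make_cwt_kernels(spec, grid, n)
  out <- array(0, dim = c(n_ch, grid$n_scales, n))
  for (ch in seq_len(n_ch)) {
    m <- Mod(cwt(window$samples[ch, ], spec, grid, kernels))
    if (squared) m <- m^2
    out[ch, , ] <- m
  }
  if (!is.null(normalization)) {
    for (ch in seq_len(n_ch))
      out[ch, , ] <- apply_channel_norm(out[ch, , ], normalization, ch)
  }
  structure(out, normalization = normalization,
            provenance = list(trial_ref = window$trial_ref,
                              family = spec$family, f_b = spec$f_b,
                              f_c = spec$f_c, m = spec$m,
                              scales = grid$scales))
}

#' Fit per-channel normalization statistics
#'
#' Computes the per-channel feature normalization used by the
#' classifier, from a (training) feature array. Non-negative magnitude
#' features (CWT scalograms) get a logarithmic compression before
#' standardization — `log1p(x / ref)` with `ref` the channel's median
#' positive magnitude — which tames the wide dynamic range of wavelet
#' magnitudes across scales; signed features (raw time-domain stacks)
#' get a plain z-score. Both transforms are invertible from the stored
#' record.
#'
#' @param features 4-D array `(n_scales, n_times, n_channels, N)` as
#'   returned by [featurize_windows()] or [time_domain_stack()].
#' @return Normalization record (`scheme`, `ref`, `mean`, `sd`) for
#'   [scalogram_stack()] / [train_cnn()].
#' @export
fit_feature_normalization <- function(features) {
  n_ch <- dim(features)[3]
  log_scheme <- min(features) >= 0
  ref <- rep(NA_real_, n_ch); m <- numeric(n_ch); s <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    v <- as.numeric(features[, , ch, , drop = FALSE])
    if (log_scheme) {
      r <- stats::median(v[v > 0])
      if (!is.finite(r) || r <= 0) r <- 1
      ref[ch] <- r
      v <- log1p(v / r)
    }
    m[ch] <- mean(v)
    s[ch] <- sd(v)
    if (!is.finite(s[ch]) || s[ch] == 0) s[ch] <- 1
  }
  list(scheme = if (log_scheme) "per_channel_log_zscore" else "per_channel_zscore",
       ref = ref, mean = m, sd = s)
}

## Apply a fit_feature_normalization() record to one channel's values.
apply_channel_norm <- function(v, norm, ch) {
  if (identical(norm$scheme, "per_channel_log_zscore"))
    v <- log1p(v / norm$ref[ch])
  else if (!identical(norm$scheme, "per_channel_zscore"))
    stop_domain("unknown normalization scheme")
  (v - norm$mean[ch]) / norm$sd[ch]
}

#' Featurize a batch of windows into a CWT scalogram array
#'
#' Applies [scalogram_stack()] to every window and arranges the result
#' as a `(n_scales, n_times, n_channels, N)` array, the layout consumed
#' by the network. Labels and subject ids are carried as attributes.
#'
#' @param windows List of `window_segment` objects (e.g.
#'   [segment_dataset()] output).
#' @inheritParams scalogram_stack
#' @return 4-D numeric array with attributes `labels` and `subjects`.
#' @export
featurize_windows <- function(windows, spec, grid, normalization = NULL,
                              squared = FALSE) {
  if (length(windows) == 0) stop_domain("no windows to featurize")
  n <- ncol(windows[[1]]$samples)
  n_ch <- nrow(windows[[1]]$samples)
  kernels <- make_cwt_kernels(spec, grid, n)
  out <- array(0, dim = c(grid$n_scales, n, n_ch, length(windows)))
  for (w in seq_along(windows)) {
    if (nrow(windows[[w]]$samples) != n_ch || ncol(windows[[w]]$samples) != n)
      stop_domain("window channel/sample count mismatch within the batch")
    sc <- scalogram_stack(windows[[w]], spec, grid, normalization, kernels, squared)
    out[, , , w] <- aperm(sc, c(2, 3, 1))
  }
  structure(out,
            labels = vapply(windows, function(w) w$trial_ref$gesture_label, character(1)),
            subjects = vapply(windows, function(w) w$trial_ref$subject_id, numeric(1)))
}

#' Raw time-domain feature array
#'
#' Arranges windows as `(1, window_len, n_channels, N)` arrays — the raw
#' time-series input used by the time-domain-vs-spectrum-map comparison.
#'
#' @param windows List of `window_segment` objects.
#' @return 4-D numeric array with attributes `labels` and `subjects`.
#' @export
time_domain_stack <- function(windows) {
  if (length(windows) == 0) stop_domain("no windows")
  n <- ncol(windows[[1]]$samples)
  n_ch <- nrow(windows[[1]]$samples)
  out <- array(0, dim = c(1L, n, n_ch, length(windows)))
  for (w in seq_along(windows))
    out[1, , , w] <- t(windows[[w]]$samples)
  structure(out,
            labels = vapply(windows, function(w) w$trial_ref$gesture_label, character(1)),
            subjects = vapply(windows, function(w) w$trial_ref$subject_id, numeric(1)))
}
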