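fams <- c("mexh", "gaus", "cmor", "shan", "fbsp", "cgau")

test_that("mother wavelets evaluate to their characteristic values", {
  # Mexican hat peak value from the unit-energy closed form 2/(sqrt(3) pi^(1/4))
  mexh <- wavelet_spec("mexh")
  expect_equal(mother_wavelet(mexh, 0), 2 / (sqrt(3) * pi^0.25), tolerance = 1e-6)
  # first Gaussian derivative is odd, so it vanishes at the origin
  expect_identical(mother_wavelet(wavelet_spec("gaus"), 0), 0)
  # Morlet has an even Gaussian envelope peaking at t = 0
  cmor <- wavelet_spec("cmor", f_b = 1, f_c = 1)
  tg <- seq(-4, 4, by = 0.125)
  psi <- mother_wavelet(cmor, tg)
  expect_equal(Mod(psi), rev(Mod(psi)), tolerance = 1e-12)
  expect_identical(which.max(Mod(psi)), which(tg == 0))
  # real vs complex families
  expect_type(mother_wavelet(mexh, c(-1, 0, 1)), "double")
  expect_type(mother_wavelet(cmor, c(-1, 0, 1)), "complex")
  expect_error(wavelet_spec("cmor", f_b = -1), "positive")
  expect_error(wavelet_spec("shan", f_c = 0), "positive")
})

test_that("all six families are admissible; mean-shifted controls are not", {
  for (f in fams) {
    ad <- admissibility_check(wavelet_spec(f))
    expect_true(ad$pass, label = paste("admissibility of", f))
    expect_true(is.finite(ad$cv_integral))
    expect_lt(ad$relative_residual, 1e-6)
  }
  # a plain Gaussian bump has a large mean: the integrand diverges at 0
  expect_false(admissibility_check(function(t) exp(-t^2))$pass)
  # a DC-offset wavelet fails even though the oscillatory part is fine
  mexh <- wavelet_spec("mexh")
  expect_false(admissibility_check(function(t) mother_wavelet(mexh, t) + 0.05)$pass)
})

test_that("scale grid maps log-spaced pseudo-frequencies and is invertible", {
  spec <- wavelet_spec("mexh")
  grid <- make_scale_grid(64, spec, 2000, 5, 1000)
  expect_length(grid$scales, 64)
  expect_true(all(diff(grid$scales) > 0))
  expect_true(all(diff(grid$pseudo_freqs_hz) < 0))

  g2 <- make_scale_grid(2, spec, 2000, 10, 1000)
  back <- spec$f_c_eff * 2000 / g2$scales
  expect_equal(back, g2$pseudo_freqs_hz, tolerance = 1e-9)
  expect_equal(g2$pseudo_freqs_hz[1], 1000, tolerance = 1e-12)
  expect_equal(g2$pseudo_freqs_hz[2], 10, tolerance = 1e-12)
  expect_error(make_scale_grid(64, spec, 2000, 5, 1100), "Nyquist")
})

test_that("fast CWT agrees with the direct Riemann-sum oracle and is linear", {
  set.seed(21)
  n <- 64
  for (f in fams) {
    spec <- wavelet_spec(f)
    grid <- make_scale_grid(16, spec, 2000, 20, 900)
    x <- rnorm(n)
    X <- cwt(x, spec, grid)
    D <- direct_cwt(x, spec, grid)
    expect_lt(max(Mod(X - D)) / max(Mod(D)), 1e-6,
              label = paste("oracle agreement for", f))
  }
  spec <- wavelet_spec("cmor")
  grid <- make_scale_grid(16, spec, 2000, 20, 900)
  expect_true(all(cwt(numeric(n), spec, grid) == 0))
  x <- rnorm(n); y <- rnorm(n); a <- 1.7; b <- -0.4
  lhs <- cwt(a * x + b * y, spec, grid)
  rhs <- a * cwt(x, spec, grid) + b * cwt(y, spec, grid)
  expect_lt(max(Mod(lhs - rhs)), 1e-10 * max(Mod(rhs)))
  expect_error(cwt(numeric(0), spec, grid), "empty")
})

test_that("interior CWT coefficients are shift-covariant", {
  set.seed(31)
  n <- 264; k <- 17
  x <- rnorm(n)
  xs <- c(numeric(k), x[1:(n - k)])
  for (f in c("mexh", "gaus", "cmor", "cgau")) {
    spec <- wavelet_spec(f)
    grid <- make_scale_grid(12, spec, 2000, 40, 600)
    X <- cwt(x, spec, grid)
    Xs <- cwt(xs, spec, grid)
    scale_max <- max(Mod(X))
    for (s in seq_len(grid$n_scales)) {
      b <- grid$scales[s]
      # support radius: where the dilated wavelet has decayed below 1e-8
      tg <- seq(0, n, by = 0.5)
      amp <- Mod(mother_wavelet(spec, tg / b))
      r <- ceiling(max(tg[amp > 1e-8 * max(amp)]))
      if (r + k + 11 > n - r) next   # support leaves no interior columns
      cols <- (r + k + 1):(n - r)
      expect_lt(max(Mod(Xs[s, cols] - X[s, cols - k])) / scale_max, 1e-6,
                label = sprintf("shift covariance %s scale %d", f, s))
    }
  }
})

test_that("a tone is detected at its pseudo-frequency scale", {
  n <- 264
  # narrow-band Morlet localizes the tone exactly at the nearest scale
  spec <- wavelet_spec("cmor", f_b = 1.5, f_c = 1)
  grid <- make_scale_grid(64, spec, 2000, 5, 1000)
  f0 <- grid$pseudo_freqs_hz[32]
  x <- sin(2 * pi * f0 * (0:(n - 1)) / 2000)
  prof <- rowMeans(Mod(cwt(x, spec, grid))[, 80:184])
  expect_identical(which.max(prof), 32L)
  # broadband Mexican hat may land one scale off (its tone-response peak
  # is offset from the spectral peak by the sqrt(scale) weighting)
  specm <- wavelet_spec("mexh")
  gridm <- make_scale_grid(64, specm, 2000, 5, 1000)
  xm <- sin(2 * pi * gridm$pseudo_freqs_hz[32] * (0:(n - 1)) / 2000)
  profm <- rowMeans(Mod(cwt(xm, specm, gridm))[, 80:184])
  expect_lte(abs(which.max(profm) - 32L), 1L)
})

test_that("spectrogram matches explicit DFT sums and conserves energy", {
  set.seed(41)
  x <- rnorm(96)
  wl <- 32
  S <- stft_spectrogram(x, rep(1, wl), hop = wl)
  expect_identical(dim(S), c(32L, 3L))
  for (fr in 1:3) {
    frame <- x[((fr - 1) * wl + 1):(fr * wl)]
    expect_equal(S[, fr], Mod(direct_dft(frame))^2, tolerance = 1e-9)
  }
  # Parseval: sum over bins = wl * frame energy for a unit rectangular window
  expect_equal(sum(S), wl * sum(x[1:96]^2), tolerance = 1e-9)
  # tone at a bin centre peaks in that bin
  f_bin <- 5L
  xt <- cos(2 * pi * f_bin * (0:(wl - 1)) / wl)
  St <- stft_spectrogram(xt, rep(1, wl))
  expect_identical(which.max(St[1:(wl / 2), 1]) - 1L, f_bin)
  expect_true(all(stft_spectrogram(numeric(64), rep(1, wl)) == 0))
  expect_error(stft_spectrogram(numeric(16), rep(1, 32)), "longer")
})

test_that("scalogram stacks have the contracted shape and are deterministic", {
  trials <- simulate_dataset(n_subjects = 1L, trials_per_gesture = 1L,
                             duration_samples = 264L, master_seed = 3L)
  w <- sliding_windows(trials[[1]])[[1]]
  spec <- wavelet_spec("mexh")
  grid <- make_scale_grid(64, spec, 2000, 5, 1000)

  sc <- scalogram_stack(w, spec, grid)
  expect_identical(dim(sc), c(6L, 64L, 264L))
  expect_true(all(is.finite(sc)) && all(sc >= 0))
  expect_identical(as.numeric(sc), as.numeric(scalogram_stack(w, spec, grid)))

  # all-zero window -> all-zero tensor
  w0 <- w; w0$samples[] <- 0
  expect_true(all(scalogram_stack(w0, spec, grid) == 0))

  # channel mismatch rejected
  w4 <- w; w4$samples <- w4$samples[1:4, ]
  expect_error(featurize_windows(list(w4, w), spec, grid), "channel")

  # magnitudes invariant to the sign of a real wavelet's normalization
  spec_neg <- spec; spec_neg$norm_const <- -spec$norm_const
  expect_equal(as.numeric(scalogram_stack(w, spec_neg, grid)), as.numeric(sc),
               tolerance = 1e-12)

  # z-score normalization is invertible from the stored statistics
  norm <- list(scheme = "per_channel_zscore", mean = rep(1, 6), sd = rep(2, 6))
  scn <- scalogram_stack(w, spec, grid, normalization = norm)
  expect_equal(as.numeric(scn) * 2 + 1, as.numeric(sc), tolerance = 1e-12)
})
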