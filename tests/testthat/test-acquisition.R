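test_that("theoretical gain matches the printed circuit formula", {
  # open gain pin and R_2 = 0 collapse both factors
  expect_equal(theoretical_gain(conditioning_components(
    R_G = Inf, R_c1 = 0, R_2 = 0, R_3 = 1000, R_c2 = 100, R_c3 = 50)), 10)
  # R_G = 49.4k makes the first factor exactly 2, any R_c3 > 0
  for (rc3 in c(1, 50, 1e4))
    expect_equal(theoretical_gain(conditioning_components(
      R_G = 49.4e3, R_c1 = 0, R_2 = 0, R_3 = 1000, R_c2 = 100, R_c3 = rc3)), 20)
  # random positive component sets vs independent term-by-term evaluation
  set.seed(42)
  for (i in 1:1000) {
    v <- runif(6, 1, 1e5)
    expect_equal(
      theoretical_gain(conditioning_components(v[1], v[2], v[3], v[4], v[5], v[6])),
      gain_by_terms(v[1], v[2], v[3], v[4], v[5], v[6]))
  }
})

test_that("degenerate or invalid circuits are rejected", {
  expect_error(theoretical_gain(conditioning_components(
    R_G = 1000, R_2 = 0, R_3 = 5, R_c1 = 0, R_c2 = 0, R_c3 = 0)),
    "degenerate")
  expect_error(conditioning_components(1000, -5, 1, 0, 1, 1), "non-negative")
  expect_error(conditioning_components(0, 5, 1, 0, 1, 1), "R_G")
})

test_that("conditioning chain amplifies mid-band by the nominal gain and rejects out-of-band", {
  cfg <- acquisition_config()
  fs <- cfg$sampling_rate_hz
  t <- (0:(4 * fs - 1)) / fs
  steady <- (2 * fs + 1):(4 * fs)

  y100 <- condition_signal(sin(2 * pi * 100 * t), cfg)
  amp100 <- sqrt(2 * mean(y100[steady]^2))
  expect_lt(abs(amp100 - cfg$nominal_gain) / cfg$nominal_gain, 0.05)

  # DC is removed by the high-pass corner
  ydc <- condition_signal(rep(1, 2 * fs), cfg)
  expect_lt(max(abs(tail(ydc, 100))), 1e-6 * cfg$nominal_gain)

  # deep sub-band tone is attenuated more than 2x relative to mid-band
  y05 <- condition_signal(sin(2 * pi * 0.5 * t), cfg)
  amp05 <- sqrt(2 * mean(y05[steady]^2))
  expect_lt(amp05, 0.5 * amp100)

  expect_error(acquisition_config(band_high_hz = 1200), "Nyquist")
})

test_that("mid-tread quantizer is exact at the grid, clipped at the rails, monotone", {
  cfg <- acquisition_config()
  expect_identical(as.numeric(quantize_signal(0, cfg)), 0)
  expect_identical(as.numeric(quantize_signal(cfg$full_scale_mv, cfg)), 32767)
  expect_identical(as.numeric(quantize_signal(-2 * cfg$full_scale_mv, cfg)), -32768)

  lsb <- adc_lsb_mv(cfg)
  set.seed(7)
  x <- runif(5000, -cfg$full_scale_mv + lsb, cfg$full_scale_mv - lsb)
  rt <- dequantize_signal(quantize_signal(x, cfg), cfg)
  expect_lte(max(abs(rt - x)), lsb / 2 + 1e-15)

  xs <- sort(runif(500, -8, 8))
  codes <- as.numeric(quantize_signal(xs, cfg))
  expect_true(all(diff(codes) >= 0))
})

test_that("simulated trials carry the stated signal statistics", {
  cfg <- acquisition_config()
  gests <- default_gesture_set()

  # no sources -> silence
  quiet_cfg <- acquisition_config(noise_rms_uv = 0)
  g0 <- gesture_spec("TF", matrix(0, 6, 1), list(c(0.05, 0.5)))
  tr0 <- simulate_trial(g0, quiet_cfg, seed = 3)
  expect_true(all(tr0$samples == 0))

  tr <- simulate_trial(gests$TF, cfg, seed = 7)
  expect_identical(dim(tr$samples), c(6L, 1364L))
  # dominant energy in 50-150 Hz; >= 99% of energy below 1 kHz
  pg <- stats::spec.pgram(stats::ts(tr$samples[1, ], frequency = cfg$sampling_rate_hz),
                          plot = FALSE, spans = 15)
  fpk <- pg$freq[which.max(pg$spec)]
  expect_gt(fpk, 50); expect_lt(fpk, 150)
  expect_gte(sum(pg$spec[pg$freq <= 1000]) / sum(pg$spec), 0.99)

  # zero-mean model and the 10 mV peak-to-peak budget
  for (ch in 1:6) {
    rms <- sqrt(mean(tr$samples[ch, ]^2))
    expect_lt(abs(mean(tr$samples[ch, ])), 3 * rms / sqrt(1364) + 1e-9)
    expect_lte(diff(range(tr$samples[ch, ])), 10)
  }

  # pure function of the seed
  expect_identical(tr$samples, simulate_trial(gests$TF, cfg, seed = 7)$samples)
  expect_false(identical(tr$samples, simulate_trial(gests$TF, cfg, seed = 8)$samples))
  expect_error(simulate_trial(gests$TF, cfg, duration_s = -1), "positive")
})

test_that("gesture fixtures are distinct and the dataset design grid is honoured", {
  gests <- default_gesture_set()
  expect_named(gests, gesture_labels())
  acts <- lapply(gests, function(g) list(g$activation, g$carrier_band_hz))
  expect_identical(anyDuplicated(acts), 0L)

  trials <- simulate_dataset(n_subjects = 2L, trials_per_gesture = 2L,
                             duration_samples = 364L, master_seed = 5L)
  expect_length(trials, 2 * 8 * 2)
  expect_identical(attr(trials, "design")$gestures, gesture_labels())
  # deterministic given the master seed
  trials2 <- simulate_dataset(n_subjects = 2L, trials_per_gesture = 2L,
                              duration_samples = 364L, master_seed = 5L)
  expect_identical(trials[[5]]$samples, trials2[[5]]$samples)
  # different subjects see different (jittered) signal statistics
  s1 <- trials[[1]]; s2 <- trials[[1 + 16]]
  expect_identical(s1$gesture_label, s2$gesture_label)
  expect_false(identical(sd(s1$samples[1, ]), sd(s2$samples[1, ])))
})
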