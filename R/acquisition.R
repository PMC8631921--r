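## acquisition_sim: synthetic multichannel sEMG trials and the sensor
## conditioning chain (instrumentation gain, band-pass, ADC, noise floor).

#' Acquisition-chain configuration
#'
#' Describes the simulated wireless sEMG sensor: sampling rate, ADC
#' resolution, nominal conditioning gain, band-pass corner frequencies,
#' input-referred noise floor and channel count. Defaults match the
#' high-precision sensor the pipeline emulates: 2 kHz sampling, 16-bit
#' conversion, x1000 conditioning gain, 5--1000 Hz band, < 1.5 uV RMS
#' short-circuit noise, six forearm channels.
#'
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param adc_bits ADC resolution in bits (>= 2).
#' @param full_scale_mv ADC full-scale in mV, referred to the electrode
#'   (i.e. after dividing out the conditioning gain); the quantizer spans
#'   `[-full_scale_mv, +full_scale_mv]`.
#' @param nominal_gain Net voltage gain of the conditioning circuit.
#' @param band_low_hz,band_high_hz Band-pass corner frequencies in Hz;
#'   must satisfy `band_low_hz < band_high_hz <= sampling_rate_hz / 2`.
#' @param noise_rms_uv Input-referred white-noise floor, uV RMS.
#' @param n_channels Number of electrode channels.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(sampling_rate_hz = 2000, adc_bits = 16L,
                               full_scale_mv = 5, nominal_gain = 1000,
                               band_low_hz = 5, band_high_hz = 1000,
                               noise_rms_uv = 1.5, n_channels = 6L) {
  cfg <- list(
    sampling_rate_hz = check_scalar_num(sampling_rate_hz, "sampling_rate_hz", positive = TRUE),
    adc_bits = check_count(adc_bits, "adc_bits", min = 2L),
    full_scale_mv = check_scalar_num(full_scale_mv, "full_scale_mv", positive = TRUE),
    nominal_gain = check_scalar_num(nominal_gain, "nominal_gain", positive = TRUE),
    band_low_hz = check_scalar_num(band_low_hz, "band_low_hz", positive = TRUE),
    band_high_hz = check_scalar_num(band_high_hz, "band_high_hz", positive = TRUE),
    noise_rms_uv = check_scalar_num(noise_rms_uv, "noise_rms_uv", nonneg = TRUE),
    n_channels = check_count(n_channels, "n_channels", min = 1L)
  )
  if (cfg$band_low_hz >= cfg$band_high_hz)
    stop_domain("band_low_hz must be < band_high_hz")
  if (cfg$band_high_hz > cfg$sampling_rate_hz / 2)
    stop_domain("band_high_hz must not exceed the Nyquist frequency")
  structure(cfg, class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "<acquisition_config> %g Hz, %d-bit ADC, gain x%g, band %g-%g Hz, noise %g uV RMS, %d channels\n",
    x$sampling_rate_hz, x$adc_bits, x$nominal_gain, x$band_low_hz,
    x$band_high_hz, x$noise_rms_uv, x$n_channels))
  invisible(x)
}

#' Conditioning-circuit component set
#'
#' Component values of the analog conditioning circuit: the
#' instrumentation-amplifier gain resistor `R_G`, resistors `R_2`, `R_3`
#' of the band-pass stage, and the impedances `R_c1`, `R_c2`, `R_c3` of
#' capacitors C1--C3 at the evaluation frequency. All in Ohm. `R_G = Inf`
#' marks an open gain-resistor pin (unity first-stage gain).
#'
#' @param R_G,R_2,R_3,R_c1,R_c2,R_c3 Component values, Ohm; finite and
#'   non-negative (`R_G` may be `Inf`).
#' @return An object of class `conditioning_components`.
#' @export
conditioning_components <- function(R_G, R_2, R_3, R_c1, R_c2, R_c3) {
  vals <- list(R_G = R_G, R_2 = R_2, R_3 = R_3,
               R_c1 = R_c1, R_c2 = R_c2, R_c3 = R_c3)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop_domain(sprintf("`%s` must be a single number", nm))
    if (v < 0) stop_domain(sprintf("`%s` must be non-negative", nm))
    if (nm != "R_G" && !is.finite(v))
      stop_domain(sprintf("`%s` must be finite", nm))
  }
  if (vals$R_G == 0) stop_domain("R_G must be > 0 (or Inf for open-circuit)")
  structure(vals, class = "conditioning_components")
}

#' Theoretical gain of the signal conditioning circuit
#'
#' Evaluates the circuit's theoretical voltage gain
#' \deqn{G = \left(\frac{49.4\times10^3}{R_G} + R_{c1} + 1\right)
#'       \frac{R_3 R_{c3}}{R_{c2}R_{c3} + R_2 R_{c2} + R_2 R_{c3} + R_2 R_3}}
#' with an open-circuit `R_G` contributing zero to the first factor.
#' The `R_{c1}` term added to a dimensionless gain is dimensionally
#' suspect but is evaluated as given; set `R_c1 = 0` for the
#' instrumentation-amplifier-only interpretation.
#'
#' @param components A [conditioning_components()] object.
#' @return The gain, a single dimensionless number.
#' @export
theoretical_gain <- function(components) {
  if (!inherits(components, "conditioning_components"))
    stop_domain("`components` must be a conditioning_components object")
  c_ <- components
  denom <- c_$R_c2 * c_$R_c3 + c_$R_2 * c_$R_c2 + c_$R_2 * c_$R_c3 + c_$R_2 * c_$R_3
  if (denom <= 0)
    stop_domain("degenerate circuit: denominator R_c2*R_c3 + R_2*R_c2 + R_2*R_c3 + R_2*R_3 must be > 0")
  first <- (if (is.finite(c_$R_G)) 49.4e3 / c_$R_G else 0) + c_$R_c1 + 1
  first * (c_$R_3 * c_$R_c3) / denom
}

## Second-order Butterworth band-pass for the conditioning chain. The
## digital upper corner is capped just below Nyquist because the bilinear
## transform cannot place a corner at Nyquist itself.
conditioning_filter <- function(config) {
  nyq <- config$sampling_rate_hz / 2
  lo <- config$band_low_hz / nyq
  hi <- min(config$band_high_hz, 0.99 * nyq) / nyq
  if (lo >= hi || lo <= 0)
    stop_domain("band edges incompatible with the sampling rate")
  signal::butter(1, c(lo, hi), type = "pass")
}

#' Apply the sensor conditioning chain to a raw signal
#'
#' Amplifies by the nominal gain and applies the second-order band-pass
#' (default corners 5--1000 Hz). With `input_referred = TRUE` the gain is
#' omitted so the output stays on the electrode-referred mV scale, which
#' is how the trial simulator uses it ahead of the ADC.
#'
#' @param raw Numeric vector or channels-by-samples matrix, mV.
#' @param config An [acquisition_config()].
#' @param causal Logical; `TRUE` (default) filters causally, `FALSE`
#'   applies the zero-phase (forward-backward) variant.
#' @param input_referred Logical; skip the gain factor.
#' @return Conditioned signal with the same shape as `raw`.
#' @export
condition_signal <- function(raw, config = acquisition_config(),
                             causal = TRUE, input_referred = FALSE) {
  if (!inherits(config, "acquisition_config"))
    stop_domain("`config` must be an acquisition_config object")
  if (!is.numeric(raw) || !all(is.finite(raw)))
    stop_domain("`raw` must be finite numeric")
  filt <- conditioning_filter(config)
  apply_f <- function(x) {
    y <- if (causal) signal::filter(filt, x) else signal::filtfilt(filt, x)
    as.numeric(y)
  }
  gain <- if (input_referred) 1 else config$nominal_gain
  if (is.matrix(raw)) {
    out <- t(apply(raw * gain, 1L, apply_f))
    dimnames(out) <- dimnames(raw)
    out
  } else {
    apply_f(raw * gain)
  }
}

#' ADC quantization step
#'
#' One least-significant bit of the mid-tread quantizer spanning
#' `[-full_scale_mv, +full_scale_mv]` with `2^adc_bits` levels.
#'
#' @param config An [acquisition_config()].
#' @return LSB size in mV.
#' @export
adc_lsb_mv <- function(config) 2 * config$full_scale_mv / 2^config$adc_bits

#' Quantize a conditioned signal to ADC codes
#'
#' Mid-tread uniform quantizer: `code = round(x / LSB)`, clipped to the
#' signed code range `[-2^(bits-1), 2^(bits-1) - 1]`. Clipping is defined
#' behaviour; the fraction of clipped samples is attached as the
#' `"clipped_fraction"` attribute.
#'
#' @param x Numeric vector or matrix, mV (electrode-referred).
#' @param config An [acquisition_config()].
#' @return Integer-valued object of the same shape as `x`.
#' @export
quantize_signal <- function(x, config = acquisition_config()) {
  if (!is.numeric(x) || !all(is.finite(x)))
    stop_domain("`x` must be finite numeric")
  lsb <- adc_lsb_mv(config)
  lo <- -2^(config$adc_bits - 1L)
  hi <- 2^(config$adc_bits - 1L) - 1
  codes <- round(x / lsb)
  clipped <- codes < lo | codes > hi
  codes[codes < lo] <- lo
  codes[codes > hi] <- hi
  structure(codes, clipped_fraction = mean(clipped))
}

#' Map ADC codes back to mV
#'
#' @param codes Integer codes from [quantize_signal()].
#' @param config An [acquisition_config()].
#' @return Numeric object of the same shape, mV.
#' @export
dequantize_signal <- function(codes, config = acquisition_config()) {
  out <- unclass(codes) * adc_lsb_mv(config)
  attr(out, "clipped_fraction") <- NULL
  out
}

#' Gesture specification for the trial simulator
#'
#' A gesture is modelled as per-channel burst envelopes riding on a
#' band-limited stochastic carrier. `activation` gives the RMS envelope
#' amplitude (mV) of every channel in every burst; `burst_times` places
#' the bursts within the trial; `carrier_band_hz` is the gesture's
#' dominant-energy band (inside the physiological 50--150 Hz range by
#' default), which encodes the spectral signature of the movement.
#'
#' @param label One of [gesture_labels()].
#' @param activation Non-negative matrix, `n_channels x n_bursts`, mV RMS.
#' @param burst_times List of `c(onset_s, duration_s)` pairs, one per burst.
#' @param carrier_band_hz Length-2 band `c(low, high)` in Hz.
#' @return An object of class `gesture_spec`.
#' @export
gesture_spec <- function(label, activation, burst_times,
                         carrier_band_hz = c(50, 150)) {
  if (!is.character(label) || length(label) != 1L || !(label %in% GESTURE_LABELS))
    stop_domain("`label` must be one of: ", paste(GESTURE_LABELS, collapse = ", "))
  activation <- as.matrix(activation)
  if (!is.numeric(activation) || any(!is.finite(activation)) || any(activation < 0))
    stop_domain("`activation` must be a non-negative numeric matrix")
  if (!is.list(burst_times) || length(burst_times) != ncol(activation))
    stop_domain("`burst_times` must be a list with one (onset, duration) pair per activation column")
  for (bt in burst_times) {
    if (length(bt) != 2L || any(!is.finite(bt)) || bt[2] <= 0 || bt[1] < 0)
      stop_domain("each burst must be c(onset_s >= 0, duration_s > 0)")
  }
  if (length(carrier_band_hz) != 2L || carrier_band_hz[1] <= 0 ||
      carrier_band_hz[1] >= carrier_band_hz[2])
    stop_domain("`carrier_band_hz` must be c(low, high) with 0 < low < high")
  structure(list(label = label, activation = activation,
                 burst_times = burst_times,
                 carrier_band_hz = as.numeric(carrier_band_hz)),
            class = "gesture_spec")
}

#' Default eight-gesture set
#'
#' Fixed activation fixtures for the eight-class vocabulary over six
#' forearm channels. Flexion gestures (TF, IF, MF) load the three flexor
#' channels (1--3), extension gestures (TE, IE, ME) the three extensor
#' channels (4--6); amplitudes overlap across classes so they are
#' learnable but not trivially separated by a single channel. Swing
#' gestures (TS, IS) reuse the activation pattern of the corresponding
#' flexion but carry a higher firing band (105--140 Hz vs 60--95 Hz), so
#' the flexion/swing pairs are distinguished by spectral content rather
#' than channel energy.
#'
#' @param n_channels Channel count; only the default 6 is supported.
#' @return Named list of [gesture_spec()] objects, one per label.
#' @export
default_gesture_set <- function(n_channels = 6L) {
  if (n_channels != 6L)
    stop_domain("default gesture fixtures are defined for 6 channels")
  low <- c(60, 95)
  high <- c(105, 140)
  bursts <- list(c(0.05, 0.55))
  pat <- list(
    TF = list(c(0.90, 0.45, 0.20, 0.08, 0.06, 0.05), low),
    TE = list(c(0.08, 0.06, 0.05, 0.90, 0.45, 0.20), low),
    TS = list(c(0.90, 0.45, 0.20, 0.08, 0.06, 0.05), high),
    IF = list(c(0.40, 0.90, 0.40, 0.06, 0.08, 0.05), low),
    IE = list(c(0.06, 0.08, 0.05, 0.40, 0.90, 0.40), low),
    IS = list(c(0.40, 0.90, 0.40, 0.06, 0.08, 0.05), high),
    MF = list(c(0.20, 0.45, 0.90, 0.05, 0.06, 0.08), low),
    ME = list(c(0.05, 0.06, 0.08, 0.20, 0.45, 0.90), low)
  )
  out <- lapply(names(pat), function(lb) {
    gesture_spec(lb, matrix(pat[[lb]][[1]], ncol = 1L), bursts,
                 carrier_band_hz = pat[[lb]][[2]])
  })
  names(out) <- names(pat)
  out
}

## Sum-of-bursts Hann envelope for one channel, sampled at fs over n samples.
burst_envelope <- function(amplitudes, burst_times, n, fs) {
  env <- numeric(n)
  t <- (seq_len(n) - 1) / fs
  for (b in seq_along(burst_times)) {
    onset <- burst_times[[b]][1]
    dur <- burst_times[[b]][2]
    inb <- t >= onset & t < onset + dur
    if (any(inb))
      env[inb] <- env[inb] +
        amplitudes[b] * 0.5 * (1 - cos(2 * pi * (t[inb] - onset) / dur))
  }
  env
}

#' Simulate one sEMG trial
#'
#' Per channel: a zero-mean Gaussian carrier band-limited to the
#' gesture's dominant-energy band, scaled to unit RMS and multiplied by
#' the channel's burst envelope (mV RMS), plus white measurement noise at
#' the configured noise floor; the sum is band-limited by the
#' conditioning filter (input-referred) and passed through the
#' quantize/dequantize ADC round trip. Deterministic given `seed`.
#'
#' @param gesture A [gesture_spec()].
#' @param config An [acquisition_config()].
#' @param duration_s Trial length in seconds; default 1364 samples at the
#'   configured rate, so that 264/100 windowing yields 12 windows.
#' @param seed Integer RNG seed.
#' @param subject_id,trial_index Provenance labels stored on the trial.
#' @return An object of class `trial_recording` with fields `samples`
#'   (`n_channels x n_samples` matrix, mV), `sampling_rate_hz`,
#'   `gesture_label`, `subject_id`, `trial_index`, `seed`.
#' @export
simulate_trial <- function(gesture, config = acquisition_config(),
                           duration_s = 1364 / config$sampling_rate_hz,
                           seed = 1L, subject_id = 1L, trial_index = 1L) {
  if (!inherits(gesture, "gesture_spec"))
    stop_domain("`gesture` must be a gesture_spec object")
  duration_s <- check_scalar_num(duration_s, "duration_s", positive = TRUE)
  fs <- config$sampling_rate_hz
  n <- round(duration_s * fs)
  if (n < 1) stop_domain("duration_s * sampling_rate_hz must be >= 1")
  n_ch <- config$n_channels
  if (nrow(gesture$activation) != n_ch)
    stop_domain("gesture activation rows must equal config n_channels")

  nyq <- fs / 2
  band <- pmin(gesture$carrier_band_hz, 0.99 * nyq) / nyq
  carrier_filt <- signal::butter(2, band, type = "pass")
  noise_mv <- config$noise_rms_uv / 1000

  samples <- with_seed(seed, {
    out <- matrix(0, n_ch, n)
    for (ch in seq_len(n_ch)) {
      carrier <- as.numeric(signal::filtfilt(carrier_filt, rnorm(n)))
      s <- sd(carrier)
      if (s > 0) carrier <- carrier / s
      env <- burst_envelope(gesture$activation[ch, ], gesture$burst_times, n, fs)
      out[ch, ] <- carrier * env + rnorm(n, sd = noise_mv)
    }
    out
  })

  conditioned <- condition_signal(samples, config, causal = TRUE, input_referred = TRUE)
  codes <- quantize_signal(conditioned, config)
  samples <- dequantize_signal(codes, config)

  structure(list(samples = samples, sampling_rate_hz = fs,
                 gesture_label = gesture$label,
                 subject_id = subject_id, trial_index = trial_index,
                 seed = as.integer(seed)),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s subject %s trial %s: %d x %d samples @ %g Hz (seed %d)\n",
              x$gesture_label, x$subject_id, x$trial_index,
              nrow(x$samples), ncol(x$samples), x$sampling_rate_hz, x$seed))
  invisible(x)
}

#' Simulate a full multi-subject dataset
#'
#' Runs [simulate_trial()] over the full design grid (default: 5 subjects
#' x 8 gestures x 25 trials). Per-subject variability is modelled as a
#' fixed lognormal jitter (sd 0.15 on the log scale) on each subject's
#' channel activation amplitudes, drawn once per subject from a seed
#' derived from the master seed, so that per-subject models face slightly
#' different signal statistics. Fully deterministic given `master_seed`.
#'
#' @param config An [acquisition_config()].
#' @param gestures Named list of [gesture_spec()] objects.
#' @param n_subjects Number of subjects.
#' @param trials_per_gesture Trials per gesture per subject.
#' @param duration_samples Trial length in samples.
#' @param master_seed Master RNG seed; per-trial seeds are derived with
#'   [derive_seed()].
#' @return List of `trial_recording` objects (subjects outermost, then
#'   gestures, then trials) with attribute `"design"` recording the
#'   grid dimensions.
#' @export
simulate_dataset <- function(config = acquisition_config(),
                             gestures = default_gesture_set(config$n_channels),
                             n_subjects = 5L, trials_per_gesture = 25L,
                             duration_samples = 1364L, master_seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  trials_per_gesture <- check_count(trials_per_gesture, "trials_per_gesture")
  duration_samples <- check_count(duration_samples, "duration_samples")
  duration_s <- duration_samples / config$sampling_rate_hz

  trials <- vector("list", n_subjects * length(gestures) * trials_per_gesture)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    jitter <- with_seed(derive_seed(master_seed, s, 0L, 0L),
                        matrix(exp(rnorm(config$n_channels, sd = 0.15)),
                               config$n_channels, 1L))
    for (g in seq_along(gestures)) {
      gs <- gestures[[g]]
      gs_subj <- gesture_spec(gs$label, sweep(gs$activation, 1L, as.numeric(jitter), "*"),
                              gs$burst_times, gs$carrier_band_hz)
      for (tr in seq_len(trials_per_gesture)) {
        k <- k + 1L
        trials[[k]] <- simulate_trial(
          gs_subj, config, duration_s,
          seed = derive_seed(master_seed, s, g, tr),
          subject_id = s, trial_index = tr)
      }
    }
  }
  structure(trials,
            design = list(n_subjects = n_subjects,
                          gestures = names(gestures),
                          trials_per_gesture = trials_per_gesture,
                          duration_samples = duration_samples,
                          master_seed = as.integer(master_seed)))
}
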