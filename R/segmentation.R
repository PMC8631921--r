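## segmentation: deterministic fixed-length sliding windows over trials.

#' Sliding-window segmentation of a trial
#'
#' Cuts a trial into fixed-length windows starting at offsets
#' `0, step, 2*step, ...`; trailing partial windows are discarded, so a
#' trial of `n` samples yields exactly `floor((n - window_len)/step) + 1`
#' windows. The defaults (264 samples = 132 ms at 2 kHz, step 100) give
#' 12 windows per 1364-sample trial. Window content is an exact slice of
#' the source trial; labels and provenance are inherited.
#'
#' @param trial A `trial_recording` from [simulate_trial()].
#' @param window_len Window length in samples.
#' @param step Increment between window starts, samples.
#' @param strict Logical; if the trial is shorter than `window_len`,
#'   `TRUE` (default) raises an error, `FALSE` returns an empty list with
#'   a warning.
#' @return List of `window_segment` objects, each with fields `samples`
#'   (`n_channels x window_len` matrix, mV), `window_len`, `step` and
#'   `trial_ref` (subject, gesture, trial index, start offset in samples,
#'   0-based).
#' @export
sliding_windows <- function(trial, window_len = 264L, step = 100L, strict = TRUE) {
  if (!inherits(trial, "trial_recording"))
    stop_domain("`trial` must be a trial_recording object")
  window_len <- check_count(window_len, "window_len")
  step <- check_count(step, "step")
  n <- ncol(trial$samples)
  if (n < window_len) {
    if (strict)
      stop_domain(sprintf("trial has %d samples, shorter than window_len = %d", n, window_len))
    warning("trial shorter than window_len; returning no windows")
    return(list())
  }
  n_win <- (n - window_len) %/% step + 1L
  lapply(seq_len(n_win), function(w) {
    start <- (w - 1L) * step          # 0-based offset
    structure(list(
      samples = trial$samples[, (start + 1L):(start + window_len), drop = FALSE],
      window_len = window_len, step = step,
      trial_ref = list(subject_id = trial$subject_id,
                       gesture_label = trial$gesture_label,
                       trial_index = trial$trial_index,
                       start_offset = start)),
      class = "window_segment")
  })
}

#' Segment every trial of a dataset
#'
#' Applies [sliding_windows()] per trial (windows never span trial
#' boundaries) and flattens the result.
#'
#' @param trials List of `trial_recording` objects, e.g. from
#'   [simulate_dataset()].
#' @inheritParams sliding_windows
#' @return List of `window_segment` objects with attributes `labels`
#'   (gesture label per window) and `subjects` (subject id per window).
#' @export
segment_dataset <- function(trials, window_len = 264L, step = 100L) {
  windows <- lapply(trials, sliding_windows, window_len = window_len, step = step)
  flat <- unlist(windows, recursive = FALSE)
  structure(flat,
            labels = vapply(flat, function(w) w$trial_ref$gesture_label, character(1)),
            subjects = vapply(flat, function(w) w$trial_ref$subject_id, numeric(1)))
}
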