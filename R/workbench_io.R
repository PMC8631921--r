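## workbench_io: plain-text dataset container (per-trial CSV + JSON
## manifest), manifest bookkeeping, and the stratified train/test split.

MANIFEST_VERSION <- "1"

#' Dataset manifest
#'
#' Bookkeeping record of a dataset design: subjects, gesture vocabulary,
#' trials per gesture, trial length, segmentation parameters and the
#' window counts they imply. Under the defaults (5 subjects, 8 gestures,
#' 25 trials, 1364-sample trials, 264/100 windowing, 80/20 split) the
#' derived counts are 12 windows/trial, 300 windows/gesture/subject,
#' 2400 windows/subject, 12000 total and 1920/480 train/test per
#' subject.
#'
#' @param n_subjects,trials_per_gesture,duration_samples Design grid.
#' @param gestures Gesture label vocabulary.
#' @param window_len,step Segmentation parameters.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param master_seed Master seed of the dataset.
#' @param train_fraction Train share of the window-level split.
#' @return An object of class `dataset_manifest`.
#' @export
dataset_manifest <- function(n_subjects = 5L, gestures = gesture_labels(),
                             trials_per_gesture = 25L, duration_samples = 1364L,
                             window_len = 264L, step = 100L,
                             sampling_rate_hz = 2000, master_seed = 1L,
                             train_fraction = 0.8) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  trials_per_gesture <- check_count(trials_per_gesture, "trials_per_gesture")
  duration_samples <- check_count(duration_samples, "duration_samples")
  window_len <- check_count(window_len, "window_len")
  step <- check_count(step, "step")
  if (duration_samples < window_len)
    stop_domain("duration_samples must be >= window_len")
  wpt <- (duration_samples - window_len) %/% step + 1L
  wpg <- wpt * trials_per_gesture
  wps <- wpg * length(gestures)
  total <- wps * n_subjects
  test_ps <- as.integer(round((1 - train_fraction) * wps))
  structure(list(
    format_version = MANIFEST_VERSION,
    subjects = seq_len(n_subjects),
    gestures = as.character(gestures),
    trials_per_gesture = trials_per_gesture,
    duration_samples = duration_samples,
    window_len = window_len, step = step,
    sampling_rate_hz = sampling_rate_hz,
    master_seed = as.integer(master_seed),
    train_fraction = train_fraction,
    windows_per_trial = wpt,
    windows_per_gesture_per_subject = wpg,
    windows_per_subject = wps,
    total_windows = total,
    train_per_subject = wps - test_ps,
    test_per_subject = test_ps), class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf(
    "<dataset_manifest v%s> %d subjects x %d gestures x %d trials; %d windows/trial; %d total; %d/%d train/test per subject\n",
    x$format_version, length(x$subjects), length(x$gestures),
    x$trials_per_gesture, x$windows_per_trial, x$total_windows,
    x$train_per_subject, x$test_per_subject))
  invisible(x)
}

#' Write a trial dataset to a plain-text container
#'
#' Container layout: `<dir>/manifest.json` plus one CSV per trial under
#' `<dir>/trials/`, columns `ch1..chK`. Trials whose samples sit exactly
#' on the ADC grid (the simulator's always do) are stored as integer ADC
#' codes with the LSB recorded in the manifest, making the round trip
#' bit-exact; other trials fall back to full-precision decimal text.
#'
#' @param trials List of `trial_recording` objects.
#' @param dir Output directory (created if missing).
#' @param config The [acquisition_config()] the trials were produced
#'   under (sets the ADC code scale).
#' @param manifest Optional [dataset_manifest()]; defaults to one built
#'   from the trials' `design` attribute when present.
#' @return `dir`, invisibly.
#' @export
write_trials <- function(trials, dir, config = acquisition_config(),
                         manifest = NULL) {
  if (length(trials) == 0) stop_domain("no trials to write")
  dir.create(file.path(dir, "trials"), recursive = TRUE, showWarnings = FALSE)
  lsb <- adc_lsb_mv(config)
  if (is.null(manifest)) {
    des <- attr(trials, "design")
    manifest <- if (!is.null(des)) {
      dataset_manifest(n_subjects = des$n_subjects, gestures = des$gestures,
                       trials_per_gesture = des$trials_per_gesture,
                       duration_samples = des$duration_samples,
                       sampling_rate_hz = config$sampling_rate_hz,
                       master_seed = des$master_seed)
    } else dataset_manifest(n_subjects = length(unique(vapply(trials, `[[`, numeric(1), "subject_id"))),
                            trials_per_gesture = 1L,
                            duration_samples = ncol(trials[[1]]$samples),
                            sampling_rate_hz = config$sampling_rate_hz)
  }
  entries <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    f <- sprintf("trials/trial_%05d.csv", i)
    codes <- tr$samples / lsb
    exact <- max(abs(codes - round(codes))) < 1e-9
    m <- if (exact) t(matrix(as.integer(round(codes)), nrow(codes)))
         else matrix(sprintf("%.17g", t(tr$samples)), ncol(tr$samples))
    dt <- data.table::as.data.table(m)
    data.table::setnames(dt, paste0("ch", seq_len(nrow(tr$samples))))
    data.table::fwrite(dt, file.path(dir, f))
    entries[[i]] <- list(file = f, subject_id = tr$subject_id,
                         gesture_label = tr$gesture_label,
                         trial_index = tr$trial_index, seed = tr$seed,
                         n_channels = nrow(tr$samples),
                         n_samples = ncol(tr$samples),
                         encoding = if (exact) "adc_code" else "mv_text")
  }
  payload <- c(unclass(manifest),
               list(lsb_mv = lsb, n_trials = length(trials), trials = entries))
  jsonlite::write_json(payload, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a trial dataset container
#'
#' Loads and validates a container written by [write_trials()]: the
#' manifest must be present with a matching format version, every
#' declared trial file must exist with the declared number of rows, and
#' the first offending record is named in the error otherwise.
#'
#' @param dir Container directory.
#' @return List of `trial_recording` objects with attribute `manifest`.
#' @export
read_trials <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop_domain("missing manifest: ", mf_path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  if (!identical(mf$format_version, MANIFEST_VERSION))
    stop_domain("manifest format version mismatch: found ",
                mf$format_version %||% "<none>")
  if (length(mf$trials) != mf$n_trials)
    stop_domain(sprintf("manifest declares %d trials but lists %d entries",
                        mf$n_trials, length(mf$trials)))
  lsb <- mf$lsb_mv
  trials <- vector("list", length(mf$trials))
  for (i in seq_along(mf$trials)) {
    e <- mf$trials[[i]]
    path <- file.path(dir, e$file)
    if (!file.exists(path))
      stop_domain("missing trial file (first offending record): ", e$file)
    dt <- data.table::fread(path)
    if (nrow(dt) != e$n_samples || ncol(dt) != e$n_channels)
      stop_domain(sprintf(
        "trial %s: expected %d samples x %d channels, found %d x %d (first offending record)",
        e$file, e$n_samples, e$n_channels, nrow(dt), ncol(dt)))
    m <- t(as.matrix(dt))
    samples <- if (identical(e$encoding, "adc_code")) m * lsb else {
      storage.mode(m) <- "double"; m
    }
    dimnames(samples) <- NULL
    trials[[i]] <- structure(list(samples = samples,
                                  sampling_rate_hz = mf$sampling_rate_hz,
                                  gesture_label = e$gesture_label,
                                  subject_id = e$subject_id,
                                  trial_index = e$trial_index,
                                  seed = as.integer(e$seed)),
                             class = "trial_recording")
  }
  attr(trials, "manifest") <- mf
  trials
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified per-subject train/test split
#'
#' Splits window indices into train and test sets per subject,
#' stratified by gesture within subject: for each (subject, gesture)
#' stratum a seeded shuffle assigns the first `round(train_fraction * n)`
#' windows to training. Disjoint and exhaustive by construction; the
#' per-gesture test counts differ from exact proportionality by at most
#' one. Under the default design (2400 windows/subject, fraction 0.8)
#' each subject gets 1920 training and 480 test windows.
#'
#' @param labels Gesture label per window.
#' @param subjects Subject id per window.
#' @param train_fraction Train share, in (0, 1).
#' @param master_seed Master seed; each subject's shuffle uses a seed
#'   derived with [derive_seed()].
#' @return Named list (one element per subject id) of
#'   `list(train =, test =)` integer index vectors into the window
#'   sequence.
#' @export
make_split <- function(labels, subjects, train_fraction = 0.8, master_seed = 1L) {
  train_fraction <- check_scalar_num(train_fraction, "train_fraction", positive = TRUE)
  if (train_fraction >= 1) stop_domain("train_fraction must be in (0, 1)")
  if (length(labels) != length(subjects))
    stop_domain("labels and subjects must have equal length")
  subj_ids <- sort(unique(subjects))
  out <- list()
  for (si in seq_along(subj_ids)) {
    s <- subj_ids[si]
    tr <- integer(0); te <- integer(0)
    for (g in sort(unique(labels[subjects == s]))) {
      idx <- which(subjects == s & labels == g)
      if (length(idx) < 2L)
        stop_domain(sprintf("stratification error: subject %s gesture %s has %d window(s)",
                            s, g, length(idx)))
      idx <- with_seed(derive_seed(master_seed, si, match(g, sort(unique(labels)))),
                       idx[sample.int(length(idx))])
      n_tr <- min(max(as.integer(round(train_fraction * length(idx))), 1L),
                  length(idx) - 1L)
      tr <- c(tr, idx[seq_len(n_tr)])
      te <- c(te, idx[(n_tr + 1L):length(idx)])
    }
    out[[as.character(s)]] <- list(train = sort(tr), test = sort(te))
  }
  out
}

#' Write / read a feature array as plain text
#'
#' Stores a 4-D feature array (plus labels and subjects) in a single
#' text file: a JSON header line with the dimensions, then one
#' full-precision value per line, so the round trip is bit-exact.
#' Intended for small exchange artifacts; large feature sets are cheaper
#' to regenerate from trials.
#'
#' @param features 4-D array from [featurize_windows()] or
#'   [time_domain_stack()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_feature_array <- function(features, file) {
  if (length(dim(features)) != 4L) stop_domain("`features` must be 4-d")
  hdr <- jsonlite::toJSON(list(dim = dim(features),
                               labels = attr(features, "labels"),
                               subjects = attr(features, "subjects")),
                          auto_unbox = FALSE, digits = NA)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  writeLines(sprintf("%.17g", as.numeric(features)), con)
  invisible(file)
}

#' @rdname write_feature_array
#' @export
read_feature_array <- function(file) {
  lines <- readLines(file)
  hdr <- jsonlite::fromJSON(lines[1])
  vals <- as.numeric(lines[-1])
  if (length(vals) != prod(hdr$dim))
    stop_domain(sprintf("feature file %s: expected %d values, found %d",
                        file, prod(hdr$dim), length(vals)))
  structure(array(vals, dim = hdr$dim),
            labels = hdr$labels, subjects = hdr$subjects)
}
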