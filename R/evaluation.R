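## evaluation: accuracy-rate statistics (AR, MAR, SD-AR), confusion
## matrices, and the model-selection grid over kernel size and mother
## wavelet.

#' Accuracy rate of one run
#'
#' Fraction of exact label matches over a test set:
#' \eqn{AR = t^{-1} \sum_i \Psi(w, f(x_i))} with the 0/1 agreement
#' indicator \eqn{\Psi}.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @return AR in `[0, 1]`.
#' @export
accuracy_rate <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop_domain("label vectors must have equal length")
  if (length(true_labels) < 1L) stop_domain("need at least one instance")
  mean(true_labels == predicted_labels)
}

#' MAR and SD-AR of a set of runs
#'
#' Mean accuracy rate \eqn{MAR = n^{-1}\sum_k AR_k} and its population
#' (1/n) standard deviation
#' \eqn{SD\mbox{-}AR = \sqrt{n^{-1}\sum_k (AR_k - MAR)^2}}, on the same
#' scale (percent or fraction) as the input. MAR summarizes
#' classification ability, SD-AR robustness across runs.
#'
#' @param per_run_ar Numeric vector of per-run accuracy rates.
#' @return List with `mar`, `sd_ar` and `n`.
#' @export
summarize_ar <- function(per_run_ar) {
  if (length(per_run_ar) < 1L) stop_domain("need at least one run")
  if (!is.numeric(per_run_ar) || any(!is.finite(per_run_ar)))
    stop_domain("`per_run_ar` must be finite numeric")
  mar <- mean(per_run_ar)
  list(mar = mar,
       sd_ar = sqrt(mean((per_run_ar - mar)^2)),
       n = length(per_run_ar))
}

#' Confusion matrix over a fixed vocabulary
#'
#' Entry `(i, j)` counts instances of true class `i` predicted as class
#' `j`; the trace divided by the total equals [accuracy_rate()].
#'
#' @param true_labels,predicted_labels Equal-length label vectors; every
#'   label must belong to `vocabulary`.
#' @param vocabulary Class vocabulary fixing row/column order.
#' @return `length(vocabulary)` square count matrix with dimnames.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             vocabulary = gesture_labels()) {
  if (length(true_labels) != length(predicted_labels))
    stop_domain("label vectors must have equal length")
  bad <- setdiff(unique(c(true_labels, predicted_labels)), vocabulary)
  if (length(bad))
    stop_domain("labels outside the vocabulary: ", paste(bad, collapse = ", "))
  ti <- factor(true_labels, levels = vocabulary)
  pi_ <- factor(predicted_labels, levels = vocabulary)
  m <- table(ti, pi_)
  out <- matrix(as.integer(m), length(vocabulary), length(vocabulary),
                dimnames = list(true = vocabulary, predicted = vocabulary))
  out
}

#' Model-selection grid over kernel sizes and mother wavelets
#'
#' For every (kernel size, wavelet family) configuration, trains one
#' per-subject model on that subject's training windows and evaluates AR
#' on its test windows, then summarizes each configuration with MAR and
#' SD-AR across subjects — the protocol behind the kernel-size and
#' wavelet comparison tables. Every (configuration, subject) run gets a
#' seed derived from `master_seed` with [derive_seed()], so the whole
#' grid is reproducible. A configuration failing upstream validation is
#' recorded as a failed row (AR `NA`), never silently skipped.
#'
#' @param trials List of `trial_recording` objects.
#' @param kernels Integer vector of kernel sizes.
#' @param wavelets Character vector of wavelet family names.
#' @param master_seed Master seed of the grid.
#' @param train_cfg [train_config()] template; its seed is replaced per
#'   run.
#' @param n_scales,f_min_hz,f_max_hz Scale-grid parameters.
#' @param window_len,step Segmentation parameters.
#' @param train_fraction Train share of the per-subject window split.
#' @return List with `runs` (data.frame: kernel, wavelet, subject, seed,
#'   ar_percent, status), `summary` (kernel, wavelet, mar, sd_ar, n) and
#'   `mode = "subjects"` (the n of the summaries is the subject count).
#' @export
run_grid <- function(trials, kernels = c(3L), wavelets = c("mexh"),
                     master_seed = 1L, train_cfg = train_config(),
                     n_scales = 64L, f_min_hz = 5, f_max_hz = 1000,
                     window_len = 264L, step = 100L, train_fraction = 0.8) {
  if (length(kernels) < 1L || length(wavelets) < 1L)
    stop_domain("kernel and wavelet grids must be non-empty")
  fs <- trials[[1]]$sampling_rate_hz
  windows <- segment_dataset(trials, window_len, step)
  labels <- attr(windows, "labels")
  subjects <- attr(windows, "subjects")
  subj_ids <- sort(unique(subjects))
  splits <- make_split(labels, subjects, train_fraction, master_seed)

  runs <- data.frame()
  for (wi in seq_along(wavelets)) {
    feats_res <- tryCatch({
      spec <- wavelet_spec(wavelets[wi])
      grid <- make_scale_grid(n_scales, spec, fs, f_min_hz, f_max_hz)
      featurize_windows(windows, spec, grid)
    }, error = function(e) e)
    for (ki in seq_along(kernels)) {
      for (si in seq_along(subj_ids)) {
        seed <- derive_seed(master_seed, ki, wi, si)
        row <- data.frame(kernel = kernels[ki], wavelet = wavelets[wi],
                          subject = subj_ids[si], seed = seed,
                          ar_percent = NA_real_, status = "failed",
                          stringsAsFactors = FALSE)
        if (!inherits(feats_res, "error")) {
          res <- tryCatch({
            sp <- splits[[as.character(subj_ids[si])]]
            cfg <- train_cfg
            cfg$seed <- seed
            mspec <- model_spec(kernel_size = kernels[ki],
                                n_input_channels = dim(feats_res)[3],
                                n_classes = length(unique(labels)))
            model <- train_cnn(feats_res[, , , sp$train, drop = FALSE],
                               labels[sp$train], mspec, cfg)
            pred <- predict(model, feats_res[, , , sp$test, drop = FALSE])
            100 * accuracy_rate(labels[sp$test], pred$labels)
          }, error = function(e) NA_real_)
          if (!is.na(res)) {
            row$ar_percent <- res
            row$status <- "ok"
          }
        }
        runs <- rbind(runs, row)
      }
    }
  }

  summary <- do.call(rbind, lapply(split(runs, list(runs$kernel, runs$wavelet), drop = TRUE),
    function(g) {
      ok <- g$ar_percent[g$status == "ok"]
      s <- if (length(ok)) summarize_ar(ok) else list(mar = NA_real_, sd_ar = NA_real_, n = 0L)
      data.frame(kernel = g$kernel[1], wavelet = g$wavelet[1],
                 mar = s$mar, sd_ar = s$sd_ar, n = s$n,
                 stringsAsFactors = FALSE)
    }))
  rownames(summary) <- NULL
  list(runs = runs, summary = summary, mode = "subjects",
       master_seed = as.integer(master_seed))
}
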