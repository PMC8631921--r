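## cnn_fgr: the compact convolutional classifier. Five convolutional
## stages (16, 32, 32, 64 feature maps, strides 1-2-1-2, channelwise
## dropout after stage 2), a final convolution onto the class maps and a
## global spatial average in place of a fully connected head. Implemented
## from scratch on im2col/GEMM convolution primitives (src/conv_ops.cpp)
## with softmax cross-entropy and Adam.

#' Network specification
#'
#' @param kernel_size Odd convolution kernel size (the model-selection
#'   grid uses 3, 5, 7, 9).
#' @param feature_maps Feature-map counts of the four hidden stages.
#' @param strides Convolution strides of the four hidden stages.
#' @param dropout_p Channelwise dropout probability applied after
#'   stage 2 (training mode only).
#' @param n_input_channels Input channels (sEMG electrode channels).
#' @param n_classes Output classes.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kernel_size = 3L, feature_maps = c(16L, 32L, 32L, 64L),
                       strides = c(1L, 2L, 1L, 2L), dropout_p = 0.5,
                       n_input_channels = 6L, n_classes = 8L) {
  kernel_size <- check_count(kernel_size, "kernel_size")
  if (kernel_size %% 2L == 0L)
    stop_domain("`kernel_size` must be odd")
  if (length(feature_maps) != 4L || length(strides) != 4L)
    stop_domain("`feature_maps` and `strides` must have length 4")
  feature_maps <- vapply(feature_maps, check_count, integer(1), name = "feature_maps")
  strides <- vapply(strides, check_count, integer(1), name = "strides")
  dropout_p <- check_scalar_num(dropout_p, "dropout_p", nonneg = TRUE)
  if (dropout_p >= 1) stop_domain("`dropout_p` must be in [0, 1)")
  structure(list(kernel_size = kernel_size, feature_maps = feature_maps,
                 strides = strides, dropout_p = dropout_p,
                 n_input_channels = check_count(n_input_channels, "n_input_channels"),
                 n_classes = check_count(n_classes, "n_classes", min = 2L)),
            class = "model_spec")
}

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param lr_decay Per-epoch multiplicative learning-rate decay factor
#'   in (0, 1]; 1 (default) keeps the rate constant.
#' @param weight_decay Decoupled (AdamW-style) weight decay coefficient
#'   applied to convolution weights; 0 (default) disables it.
#' @param batch_size Minibatch size.
#' @param max_epochs Upper bound on training epochs.
#' @param seed RNG seed controlling initialization, the internal
#'   train/validation split, shuffling and dropout; training is a pure
#'   function of it.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param train_fraction Fraction of the supplied data used for the
#'   gradient updates; the rest monitors early stopping.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, lr_decay = 1, weight_decay = 0,
                         batch_size = 32L, max_epochs = 150L, seed = 1L,
                         patience = 20L, train_fraction = 0.8) {
  tf <- check_scalar_num(train_fraction, "train_fraction", positive = TRUE)
  if (tf >= 1) stop_domain("`train_fraction` must be in (0, 1)")
  lr_decay <- check_scalar_num(lr_decay, "lr_decay", positive = TRUE)
  if (lr_decay > 1) stop_domain("`lr_decay` must be in (0, 1]")
  structure(list(learning_rate = check_scalar_num(learning_rate, "learning_rate", positive = TRUE),
                 lr_decay = lr_decay,
                 weight_decay = check_scalar_num(weight_decay, "weight_decay", nonneg = TRUE),
                 batch_size = check_count(batch_size, "batch_size"),
                 max_epochs = check_count(max_epochs, "max_epochs"),
                 seed = check_count(seed, "seed", min = 0L),
                 patience = check_count(patience, "patience"),
                 train_fraction = tf),
            class = "train_config")
}

## Layer table: (Cin, Cout, stride) of the five convolutions.
cnn_layers <- function(spec) {
  fm <- spec$feature_maps
  list(
    list(cin = spec$n_input_channels, cout = fm[1], stride = spec$strides[1]),
    list(cin = fm[1], cout = fm[2], stride = spec$strides[2]),
    list(cin = fm[2], cout = fm[3], stride = spec$strides[3]),
    list(cin = fm[3], cout = fm[4], stride = spec$strides[4]),
    list(cin = fm[4], cout = spec$n_classes, stride = 1L))
}

#' Build an untrained network
#'
#' Allocates He-initialized parameters for the five-stage architecture.
#' The global-average-pooled head makes the output dimension `n_classes`
#' for any input spatial size.
#'
#' @param spec A [model_spec()].
#' @param seed Seed for the parameter initialization.
#' @return An object of class `cnn_model` with fields `spec`, `params`
#'   (per-layer `w` `(k, k, Cin, Cout)` arrays and `b` vectors).
#' @export
build_cnn <- function(spec = model_spec(), seed = 1L) {
  if (!inherits(spec, "model_spec")) stop_domain("`spec` must be a model_spec")
  k <- spec$kernel_size
  layers <- cnn_layers(spec)
  params <- with_seed(seed, lapply(layers, function(l) {
    fan_in <- k * k * l$cin
    list(w = array(rnorm(k * k * l$cin * l$cout, sd = sqrt(2 / fan_in)),
                   dim = c(k, k, l$cin, l$cout)),
         b = numeric(l$cout))
  }))
  structure(list(spec = spec, params = params), class = "cnn_model")
}

#' Number of learned parameters
#'
#' @param model A `cnn_model` or `trained_model`.
#' @return Total count of weights and biases.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$w) + length(p$b), numeric(1)))
}

## Forward pass. `training` enables channelwise dropout (mask drawn from
## the current RNG stream) after stage 2. Returns class scores (n_classes
## x N) plus the caches needed for backprop.
cnn_forward <- function(model, x, training = FALSE) {
  spec <- model$spec
  k <- spec$kernel_size
  pad <- k %/% 2L
  layers <- cnn_layers(spec)
  acts <- vector("list", 6L)  # acts[[l]] = input to layer l
  acts[[1]] <- x
  dropout_mask <- NULL
  for (l in 1:5) {
    y <- conv2d_forward(acts[[l]], model$params[[l]]$w, model$params[[l]]$b,
                        layers[[l]]$stride, pad, relu = l <= 4L)
    if (l == 2L && training && spec$dropout_p > 0) {
      d <- dim(y)
      keep <- matrix(runif(d[3] * d[4]) >= spec$dropout_p, d[3], d[4])
      dropout_mask <- keep / (1 - spec$dropout_p)
      y <- y * array(rep(dropout_mask, each = d[1] * d[2]), dim = d)
    }
    acts[[l + 1]] <- y
  }
  y5 <- acts[[6]]
  d5 <- dim(y5)
  hw <- d5[1] * d5[2]
  scores <- matrix(colMeans(matrix(y5, nrow = hw)), d5[3], d5[4])
  list(scores = scores, acts = acts, dropout_mask = dropout_mask)
}

## Backward pass from dscores (n_classes x N); returns per-layer grads.
cnn_backward <- function(model, fwd, dscores) {
  spec <- model$spec
  k <- spec$kernel_size
  pad <- k %/% 2L
  layers <- cnn_layers(spec)
  d5 <- dim(fwd$acts[[6]])
  hw <- d5[1] * d5[2]
  dy <- array(rep(as.numeric(dscores) / hw, each = hw), dim = d5)
  grads <- vector("list", 5L)
  for (l in 5:1) {
    if (l == 2L && !is.null(fwd$dropout_mask)) {
      d <- dim(dy)
      dy <- dy * array(rep(fwd$dropout_mask, each = d[1] * d[2]), dim = d)
    }
    ## ReLU gating (hidden stages) happens inside conv2d_backward, keyed
    ## on the cached post-activation output.
    bk <- conv2d_backward(fwd$acts[[l]], model$params[[l]]$w, fwd$acts[[l + 1]],
                          dy, layers[[l]]$stride, pad,
                          relu = l <= 4L, want_dx = l > 1L)
    grads[[l]] <- list(w = bk$dw, b = bk$db)
    if (l > 1L) dy <- bk$dx
  }
  grads
}

softmax_cols <- function(scores) {
  z <- exp(sweep(scores, 2L, apply(scores, 2L, max)))
  sweep(z, 2L, colSums(z), "/")
}

#' Cross-entropy loss against one-hot targets
#'
#' Mean over the batch of the negative log predicted probability on the
#' true class: \eqn{-\sum_i y_i \log y_i'} with one-hot \eqn{y}. A zero
#' probability on the true class is clamped to `1e-12` (with a message)
#' rather than returning infinity.
#'
#' @param predicted_probs Probability vector, or matrix with one column
#'   per sample; each column must be positive and sum to 1.
#' @param one_hot Indicator vector/matrix of the same shape.
#' @return Non-negative scalar loss.
#' @export
cross_entropy_loss <- function(predicted_probs, one_hot) {
  p <- as.matrix(predicted_probs)
  y <- as.matrix(one_hot)
  if (!all(dim(p) == dim(y))) stop_domain("probability and target shapes differ")
  if (any(p < 0)) stop_domain("probabilities must be non-negative")
  if (any(abs(colSums(p) - 1) > 1e-6))
    stop_domain("each probability column must sum to 1")
  if (!all(colSums(y) == 1) || !all(y %in% c(0, 1)))
    stop_domain("targets must be one-hot")
  p_true <- colSums(p * y)
  if (any(p_true == 0)) {
    message("cross_entropy_loss: zero probability on true class clamped to 1e-12")
    p_true <- pmax(p_true, 1e-12)
  }
  mean(-log(p_true))
}

## Resolve the class vocabulary: gesture order when labels are gestures,
## sorted order otherwise.
resolve_classes <- function(labels) {
  u <- unique(labels)
  if (all(u %in% GESTURE_LABELS)) GESTURE_LABELS[GESTURE_LABELS %in% u]
  else sort(u)
}

normalize_features <- function(x, norm) {
  for (ch in seq_len(dim(x)[3]))
    x[, , ch, ] <- apply_channel_norm(x[, , ch, ], norm, ch)
  x
}

#' Train the classifier
#'
#' Trains a [build_cnn()] network on a feature array with softmax
#' cross-entropy and Adam. The supplied data are split internally
#' (stratified by label) into gradient and early-stopping monitoring
#' portions; per-channel standardization statistics are fit on the
#' gradient portion and stored with the model, so raw feature arrays are
#' passed both here and to [predict.trained_model()]. Training is
#' deterministic given `config$seed`.
#'
#' @param features 4-D array `(H, W, C, N)`: CWT scalograms
#'   `(64, 264, 6, N)` or raw time-domain stacks `(1, 264, 6, N)`.
#' @param labels Character vector of class labels, length `N`; may also
#'   be carried as the `labels` attribute of `features`.
#' @param spec A [model_spec()].
#' @param config A [train_config()].
#' @return An object of class `trained_model`: `spec`, `params`,
#'   `classes`, `normalization`, `history` (data.frame with columns
#'   epoch, train_loss, train_acc, val_acc), `best_epoch`.
#' @export
train_cnn <- function(features, labels = attr(features, "labels"),
                      spec = model_spec(), config = train_config()) {
  if (length(dim(features)) != 4L) stop_domain("`features` must be a 4-d array")
  n <- dim(features)[4]
  if (is.null(labels) || length(labels) != n)
    stop_domain("`labels` must give one label per feature tensor")
  labels <- as.character(labels)
  classes <- resolve_classes(labels)
  if (length(classes) < 2L) stop_domain("need at least 2 classes to train")
  if (dim(features)[3] != spec$n_input_channels)
    stop_domain("feature channel count does not match the model spec")
  spec$n_classes <- length(classes)
  yi <- match(labels, classes)

  with_seed(config$seed, {
    ## stratified internal split
    val_idx <- integer(0)
    for (cl in seq_along(classes)) {
      idx <- which(yi == cl)
      idx <- idx[sample.int(length(idx))]
      n_val <- max(0L, length(idx) - round(config$train_fraction * length(idx)))
      val_idx <- c(val_idx, head(idx, n_val))
    }
    tr_idx <- setdiff(seq_len(n), val_idx)

    norm <- fit_feature_normalization(features[, , , tr_idx, drop = FALSE])
    xall <- normalize_features(features, norm)
    xtr <- xall[, , , tr_idx, drop = FALSE]
    ytr <- yi[tr_idx]
    xval <- if (length(val_idx)) xall[, , , val_idx, drop = FALSE]
    yval <- yi[val_idx]

    model <- build_cnn(spec, seed = sample.int(2^30, 1L))
    adam <- lapply(model$params, function(p)
      list(mw = array(0, dim(p$w)), vw = array(0, dim(p$w)),
           mb = numeric(length(p$b)), vb = numeric(length(p$b))))
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L

    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          train_acc = numeric(0), val_acc = numeric(0))
    best <- list(acc = -Inf, params = model$params, epoch = 0L)
    stall <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      lr_epoch <- config$learning_rate *
        (config$lr_decay %||% 1)^(epoch - 1)
      ord <- sample.int(length(ytr))
      losses <- numeric(0)
      n_correct <- 0L
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        bidx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        xb <- xtr[, , , bidx, drop = FALSE]
        yb <- ytr[bidx]
        fwd <- cnn_forward(model, xb, training = TRUE)
        probs <- softmax_cols(fwd$scores)
        onehot <- matrix(0, nrow(probs), length(yb))
        onehot[cbind(yb, seq_along(yb))] <- 1
        losses <- c(losses, mean(-log(pmax(colSums(probs * onehot), 1e-12))))
        n_correct <- n_correct + sum(max.col(t(fwd$scores), "first") == yb)
        dscores <- (probs - onehot) / length(yb)
        grads <- cnn_backward(model, fwd, dscores)
        step <- step + 1L
        bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
        for (l in seq_along(model$params)) {
          a <- adam[[l]]; g <- grads[[l]]
          a$mw <- beta1 * a$mw + (1 - beta1) * g$w
          a$vw <- beta2 * a$vw + (1 - beta2) * g$w^2
          a$mb <- beta1 * a$mb + (1 - beta1) * g$b
          a$vb <- beta2 * a$vb + (1 - beta2) * g$b^2
          model$params[[l]]$w <- model$params[[l]]$w -
            lr_epoch * (a$mw / bc1) / (sqrt(a$vw / bc2) + eps) -
            lr_epoch * (config$weight_decay %||% 0) * model$params[[l]]$w
          model$params[[l]]$b <- model$params[[l]]$b -
            lr_epoch * (a$mb / bc1) / (sqrt(a$vb / bc2) + eps)
          adam[[l]] <- a
        }
      }
      train_acc <- n_correct / length(ytr)
      val_acc <- if (length(val_idx)) {
        scores <- cnn_forward(model, xval, training = FALSE)$scores
        mean(max.col(t(scores), "first") == yval)
      } else train_acc
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(losses),
        train_acc = train_acc, val_acc = val_acc))
      if (val_acc > best$acc + 1e-12) {
        best <- list(acc = val_acc, params = model$params, epoch = epoch)
        stall <- 0L
      } else stall <- stall + 1L
      if (stall >= config$patience) break
      if (train_acc >= 1 && val_acc >= 1) break   # nothing left to learn
    }

    structure(list(spec = spec, params = best$params, classes = classes,
                   normalization = norm, history = history,
                   best_epoch = best$epoch, config = config),
              class = "trained_model")
  })
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %d classes, kernel %d, %d parameters, best epoch %d (val acc %.3f)\n",
              length(x$classes), x$spec$kernel_size, count_parameters(x),
              x$best_epoch, max(x$history$val_acc)))
  invisible(x)
}

#' Predict gesture labels
#'
#' Evaluation-mode forward pass (dropout disabled, deterministic):
#' softmax class probabilities and the argmax label, ties broken toward
#' the lowest class index.
#'
#' @param object A `trained_model`.
#' @param features 4-D array `(H, W, C, N)` or a single 3-D tensor
#'   `(H, W, C)`; raw (unnormalized) scale, as in [train_cnn()].
#' @param batch_size Internal evaluation batch size.
#' @param ... Unused.
#' @return List with `labels` (character, length N) and `probs`
#'   (`n_classes x N` matrix, columns summing to 1).
#' @export
predict.trained_model <- function(object, features, batch_size = 64L, ...) {
  if (length(dim(features)) == 3L)
    features <- array(features, dim = c(dim(features), 1L))
  if (length(dim(features)) != 4L)
    stop_domain("`features` must be a 3-d tensor or 4-d batch array")
  if (dim(features)[3] != object$spec$n_input_channels)
    stop_domain("feature channel count does not match the model")
  x <- normalize_features(features, object$normalization)
  n <- dim(x)[4]
  model <- structure(list(spec = object$spec, params = object$params),
                     class = "cnn_model")
  probs <- matrix(0, length(object$classes), n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    scores <- cnn_forward(model, x[, , , idx, drop = FALSE], training = FALSE)$scores
    probs[, idx] <- softmax_cols(scores)
  }
  list(labels = object$classes[max.col(t(probs), "first")], probs = probs)
}
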