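test_that("architecture contracts: output size, parameter count, size-agnostic head", {
  expect_error(model_spec(kernel_size = 4), "odd")
  spec <- model_spec()
  model <- build_cnn(spec, seed = 1)

  s1 <- semgfgr:::cnn_forward(model, array(1, c(64, 264, 6, 1)))$scores
  expect_identical(dim(s1), c(8L, 1L))
  # global averaging makes the head independent of the spatial size
  s2 <- semgfgr:::cnn_forward(model, array(1, c(32, 132, 6, 1)))$scores
  expect_identical(dim(s2), c(8L, 1L))

  # hand-computed parameter count: sum over layers of k^2*Cin*Cout + Cout
  k <- 3
  hand <- k^2 * 6 * 16 + 16 + k^2 * 16 * 32 + 32 + k^2 * 32 * 32 + 32 +
    k^2 * 32 * 64 + 64 + k^2 * 64 * 8 + 8
  expect_identical(count_parameters(model), hand)

  # two stride-2 stages quarter each spatial dimension (same-padding)
  fwd <- semgfgr:::cnn_forward(model, array(0, c(64, 264, 6, 1)))
  expect_identical(dim(fwd$acts[[5]])[1:2], c(16L, 66L))
})

test_that("cross-entropy agrees with its closed forms and is class-permutation invariant", {
  expect_equal(cross_entropy_loss(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(cross_entropy_loss(rep(1 / 8, 8), c(1, rep(0, 7))), log(8))
  p <- c(0.7, 0.2, 0.1)
  expect_equal(cross_entropy_loss(p, c(1, 0, 0)), -log(0.7))
  # joint permutation of prediction and target leaves the loss unchanged
  perm <- c(3, 1, 2)
  expect_equal(cross_entropy_loss(p[perm], c(1, 0, 0)[perm]),
               cross_entropy_loss(p, c(1, 0, 0)))
  expect_message(
    expect_equal(cross_entropy_loss(c(0, 1), c(1, 0)), -log(1e-12)),
    "clamped")
  expect_error(cross_entropy_loss(c(0.5, 0.4), c(1, 0)), "sum to 1")
})

test_that("training is deterministic and drives a separable problem to zero error", {
  dat <- tiny_feature_set()
  cfg <- train_config(max_epochs = 50L, batch_size = 8L, seed = 5L, patience = 50L)
  spec <- model_spec()
  m1 <- train_cnn(dat$x, dat$labels, spec, cfg)
  expect_equal(tail(m1$history$train_acc, 1), 1.0)
  expect_lte(nrow(m1$history), 50L)

  m2 <- train_cnn(dat$x, dat$labels, spec, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)

  # loss trend: the last third of epochs sits below the first third
  h <- m1$history$train_loss
  thirds <- max(1L, length(h) %/% 3L)
  expect_lt(mean(tail(h, thirds)), mean(head(h, thirds)))

  expect_error(train_cnn(dat$x, rep("A", length(dat$labels)), spec, cfg),
               "2 classes")
})

test_that("evaluation-mode prediction is a deterministic probability model", {
  dat <- tiny_feature_set()
  m <- train_cnn(dat$x, dat$labels, model_spec(),
                 train_config(max_epochs = 10L, batch_size = 8L, seed = 5L))
  pr <- predict(m, dat$x)
  expect_equal(colSums(pr$probs), rep(1, dim(dat$x)[4]), tolerance = 1e-6)
  # batch of one equals the single-item call
  pr1 <- predict(m, dat$x[, , , 1])
  expect_equal(pr$probs[, 1], pr1$probs[, 1], tolerance = 1e-12)
  # dropout is off in evaluation mode: repeated passes are identical
  reps <- replicate(10, predict(m, dat$x[, , , 1:2])$probs)
  expect_true(all(apply(reps, c(1, 2), function(v) length(unique(v)) == 1L)))
  expect_error(predict(m, array(0, c(4, 4, 3, 1))), "channel")
})

test_that("analytic gradients match central differences on a 2-class micro-model", {
  spec <- model_spec(kernel_size = 3L, feature_maps = c(2L, 3L, 2L, 3L),
                     strides = c(1L, 2L, 1L, 1L), dropout_p = 0,
                     n_input_channels = 2L, n_classes = 2L)
  model <- build_cnn(spec, seed = 3)
  set.seed(4)
  x <- array(rnorm(6 * 9 * 2 * 3), c(6, 9, 2, 3))
  y <- c(1L, 2L, 1L)

  lossfn <- function(m) {
    fwd <- semgfgr:::cnn_forward(m, x, training = FALSE)
    p <- semgfgr:::softmax_cols(fwd$scores)
    oh <- matrix(0, 2, 3); oh[cbind(y, 1:3)] <- 1
    list(loss = mean(-log(colSums(p * oh))), fwd = fwd, p = p, oh = oh)
  }
  gates <- function(fwd) lapply(fwd$acts[2:5], function(a) a > 0)
  r <- lossfn(model)
  g0 <- gates(r$fwd)
  grads <- semgfgr:::cnn_backward(model, r$fwd, (r$p - r$oh) / 3)

  eps <- 1e-6; checked <- 0L
  set.seed(5)
  for (l in 1:5) {
    for (j in sample(length(model$params[[l]]$w), 15)) {
      m2 <- model; m2$params[[l]]$w[j] <- m2$params[[l]]$w[j] + eps
      m3 <- model; m3$params[[l]]$w[j] <- m3$params[[l]]$w[j] - eps
      r2 <- lossfn(m2); r3 <- lossfn(m3)
      # skip coordinates whose perturbation flips a ReLU gate: the loss is
      # not differentiable there and central differences are meaningless
      if (!identical(gates(r2$fwd), g0) || !identical(gates(r3$fwd), g0)) next
      num <- (r2$loss - r3$loss) / (2 * eps)
      expect_lt(abs(num - grads[[l]]$w[j]) / max(1e-6, abs(num), abs(grads[[l]]$w[j])),
                1e-4)
      checked <- checked + 1L
    }
    b2 <- model; b2$params[[l]]$b[1] <- b2$params[[l]]$b[1] + eps
    b3 <- model; b3$params[[l]]$b[1] <- b3$params[[l]]$b[1] - eps
    r2 <- lossfn(b2); r3 <- lossfn(b3)
    if (identical(gates(r2$fwd), g0) && identical(gates(r3$fwd), g0)) {
      num <- (r2$loss - r3$loss) / (2 * eps)
      expect_lt(abs(num - grads[[l]]$b[1]) / max(1e-6, abs(num), abs(grads[[l]]$b[1])),
                1e-4)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 50L)
})
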