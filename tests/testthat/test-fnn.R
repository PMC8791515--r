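lambda <- 1.0507009873554805
alpha <- 1.6732632423543772

test_that("selu matches its closed form and saturation limit", {
  expect_equal(selu(0), 0)
  expect_equal(selu(1), 1.0507010, tolerance = 1e-6)
  expect_equal(selu(-30), -lambda * alpha, tolerance = 1e-4)
  v <- c(-2, -0.5, 0, 0.5, 2)
  expect_equal(selu(v), ifelse(v > 0, lambda * v, lambda * alpha * (exp(v) - 1)))
  # continuity at 0
  expect_lt(abs(selu(1e-12) - selu(-1e-12)), 1e-11)
})

test_that("softmax2 is a shift-invariant probability pair", {
  expect_equal(softmax2(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax2(c(log(2), 0)), c(2 / 3, 1 / 3), tolerance = 1e-12)
  withr::with_seed(2, z <- rnorm(2))
  expect_equal(softmax2(z + 17.3), softmax2(z), tolerance = 1e-12)
  expect_equal(sum(softmax2(c(100, -100))), 1, tolerance = 1e-12)
})

test_that("binary cross-entropy matches closed forms and class-swap symmetry", {
  expect_lt(bce_loss(c(0, 1), c(0, 1)), 1e-9)
  expect_equal(bce_loss(c(0.5, 0.5), c(0, 1)), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(c(0.5, 0.5), c(1, 0)), log(2), tolerance = 1e-12)
  p <- c(0.3, 0.7)
  expect_equal(bce_loss(p, c(0, 1)), bce_loss(rev(p), c(1, 0)), tolerance = 1e-12)
  expect_true(is.finite(bce_loss(c(1, 0), c(0, 1)))) # clamped at eps
})

test_that("initialization is seeded, zero-biased, with 1/fan-in weight SD", {
  cfg <- fnn_config(width = 400, seed = 123, epochs = 0)
  m1 <- init_fnn(cfg, 476)
  m2 <- init_fnn(cfg, 476)
  expect_identical(m1$weights, m2$weights)
  for (b in m1$biases) expect_true(all(b == 0))
  expect_equal(sd(m1$weights[[1]]), 1 / 476, tolerance = 0.2)
  expect_equal(sd(m1$weights[[2]]), 1 / 400, tolerance = 0.2)
  expect_equal(dim(m1$weights[[1]]), c(476L, 400L))
  expect_equal(dim(m1$weights[[3]]), c(400L, 2L))
})

test_that("forward pass is symmetric at zero weights and deterministic at inference", {
  cfg <- fnn_config(width = 6, seed = 1, epochs = 0)
  m <- init_fnn(cfg, 10)
  m$weights <- lapply(m$weights, function(w) w * 0)
  x <- rnorm(10)
  expect_equal(as.numeric(forward(m, x)), c(0.5, 0.5))

  m2 <- init_fnn(cfg, 10)
  p1 <- forward(m2, x)
  p2 <- forward(m2, x)
  expect_identical(p1, p2)
  withr::with_seed(3, X <- matrix(rnorm(50), 5, 10))
  expect_equal(rowSums(forward(m2, X)), rep(1, 5), tolerance = 1e-12)
  # with keep probability 1, a training pass equals inference
  m2$config$dropout_keep <- 1
  expect_equal(withr::with_seed(1, forward(m2, X, training = TRUE)),
               forward(m2, X))
  expect_error(forward(m2, rnorm(7)), "channels")
})

test_that("adagrad steps start near lr and shrink as 1/sqrt(t)", {
  cfg <- fnn_config(width = 3, seed = 2, epochs = 0)
  m <- init_fnn(cfg, 4)
  g0 <- lapply(m$weights, function(w) array(0, dim(w)))
  b0 <- lapply(m$biases, function(b) numeric(length(b)))
  same <- adagrad_step(m, list(gw = g0, gb = b0), 0.05)
  expect_equal(same$weights, m$weights)

  g <- lapply(m$weights, function(w) array(0.3, dim(w)))
  stepped <- adagrad_step(m, list(gw = g, gb = b0), 0.05)
  expect_equal(abs(stepped$weights[[1]] - m$weights[[1]])[1, 1], 0.05,
               tolerance = 1e-6)
  # repeated identical gradients: t-th step magnitude ~ lr / sqrt(t)
  cur <- m
  prev <- m$weights[[1]][1, 1]
  steps <- numeric(5)
  for (t in 1:5) {
    cur <- adagrad_step(cur, list(gw = g, gb = b0), 0.05)
    steps[t] <- abs(cur$weights[[1]][1, 1] - prev)
    prev <- cur$weights[[1]][1, 1]
  }
  expect_equal(steps, 0.05 / sqrt(1:5), tolerance = 1e-4)
  g_bad <- g; g_bad[[1]][1] <- NaN
  expect_error(adagrad_step(m, list(gw = g_bad, gb = b0), 0.05), "finite")
})

test_that("backpropagated gradients match central finite differences", {
  cfg <- fnn_config(n_hidden_layers = 2, width = 4, seed = 7, epochs = 0)
  m <- init_fnn(cfg, 5)
  withr::with_seed(42, x <- rnorm(5))
  for (label in c("malignant", "benign")) {
    g <- fnn_gradients(m, x, label)
    ideal <- if (label == "malignant") c(0, 1) else c(1, 0)
    h <- 1e-6
    worst <- 0
    for (l in seq_along(m$weights)) {
      for (k in seq_len(min(8, length(m$weights[[l]])))) {
        up <- m; up$weights[[l]][k] <- up$weights[[l]][k] + h
        dn <- m; dn$weights[[l]][k] <- dn$weights[[l]][k] - h
        fd <- (bce_loss(forward(up, x)[1, ], ideal) -
                 bce_loss(forward(dn, x)[1, ], ideal)) / (2 * h)
        worst <- max(worst, abs(fd - g$gw[[l]][k]) / max(abs(fd), 1e-8))
      }
      for (k in seq_along(m$biases[[l]])) {
        up <- m; up$biases[[l]][k] <- as.numeric(up$biases[[l]])[k] + h
        dn <- m; dn$biases[[l]][k] <- as.numeric(dn$biases[[l]])[k] - h
        fd <- (bce_loss(forward(up, x)[1, ], ideal) -
                 bce_loss(forward(dn, x)[1, ], ideal)) / (2 * h)
        worst <- max(worst, abs(fd - as.numeric(g$gb[[l]])[k]) / max(abs(fd), 1e-8))
      }
    }
    expect_lt(worst, 1e-5)
  }
})

test_that("training separates a separable dataset and is reproducible", {
  d <- toy_spectra(n_per_class = 30, L = 24, gap = 2, noise = 0.2, seed = 10)
  cfg <- fnn_config(width = 16, learning_rate = 0.01, epochs = 200, seed = 5)
  fit <- train_fnn(d, config = cfg)
  expect_gte(mean(predict(fit, d)$class == d$labels), 0.98)
  expect_true(all(is.finite(fit$history$loss)))
  expect_prob_pairs(predict(fit, d), tol = 1e-12)

  fit2 <- train_fnn(d, config = cfg)
  expect_identical(fit$weights, fit2$weights)
  expect_identical(fit$history$loss, fit2$history$loss)

  frozen <- train_fnn(d, config = fnn_config(width = 16, epochs = 0, seed = 5))
  expect_identical(frozen$weights,
                   init_fnn(fnn_config(width = 16, epochs = 0, seed = 5), 24)$weights)
  single <- class_subset(d, "benign")
  expect_error(train_fnn(single, config = cfg), "both classes")
})

test_that("validation history tracks accuracy when a validation set is given", {
  d <- toy_spectra(n_per_class = 20, seed = 12)
  plan <- make_splits(d$labels, 1, 1, seed = 2)
  fit <- train_fnn(subset_samples(d, plan$train[[1]]),
                   val = subset_samples(d, plan$val[[1]]),
                   config = fnn_config(width = 8, epochs = 30, seed = 3))
  expect_equal(nrow(fit$history), 30)
  expect_true(all(fit$history$val_accuracy >= 0 & fit$history$val_accuracy <= 1))
  expect_equal(nrow(tidy(fit)), 30)
  expect_equal(glance(fit)$epochs, 30)
})

test_that("hyperparameter grids reproduce the printed sets", {
  rates <- learning_rate_grid()
  expect_equal(rates, c(1, 0.5, 0.1, 0.05, 0.01, 0.005, 0.001, 5e-4, 1e-4, 5e-5))
  expect_length(rates, 10)
  expect_equal(min(rates), 5e-5)
  widths <- layer_width_grid()
  expect_length(widths, 20)
  expect_equal(widths[1], 10)
  expect_equal(widths[20], 462)
  expect_true(all(diff(widths) > 0))
})

test_that("grid search returns the only candidate pair and a full surface", {
  d <- toy_spectra(n_per_class = 15, seed = 20)
  gs <- grid_search_fnn(d, depths = 2, rates = 0.01, widths = 8,
                        trials = 1, folds = 2, epochs = 40, seed = 4)
  expect_equal(nrow(gs$surface), 1)
  expect_equal(gs$best$learning_rate, 0.01)
  expect_equal(gs$best$width, 8)

  gs2 <- grid_search_fnn(d, depths = 2, rates = c(0.01, 0.05), widths = c(4, 8),
                         trials = 1, folds = 2, epochs = 20, seed = 4)
  expect_equal(nrow(gs2$surface), 4)
  expect_s3_class(autoplot(gs2), "ggplot")
})
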