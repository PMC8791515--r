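# The six benchmark classifiers share a contract: fit on a spectra object,
# predict probability pairs summing to 1, deterministic given a seed.

test_that("LDA separates well-separated two-band classes", {
  d <- simulate_dataset(40, 40, bands = dominant_band_config(), seed = 14)
  fit <- fit_lda(preprocess(d))
  test <- preprocess(simulate_dataset(60, 60, bands = dominant_band_config(),
                                      seed = 15))
  pr <- predict(fit, test)
  expect_gte(mean(pr$class == test$labels), 0.95)
  expect_prob_pairs(pr)
  expect_gt(fit$malignant["sigma"], 0)
  expect_gt(fit$benign["sigma"], 0)
})

test_that("LDA prediction follows the class-density softmax closed form", {
  d <- toy_spectra(n_per_class = 10, L = 8, seed = 3)
  fit <- fit_lda(d)
  # symmetric point: equidistant from both class means with equal sigma
  fit$malignant <- c(mu = -1, sigma = 0.5)
  fit$benign <- c(mu = 1, sigma = 0.5)
  sc <- matrix(c(0, 0), 1) # projects to gamma = 0, equidistant
  sc <- sc %*% diag(2) # keep as 1x2 score matrix
  pr <- predict(fit, sc)
  expect_equal(pr$p_malignant, 0.5, tolerance = 1e-9)

  # hand-evaluated normal densities at an asymmetric point
  g <- drop(c(0.3, -0.2) %*% fit$fisher_direction)
  dm <- dnorm(g, -1, 0.5)
  db <- dnorm(g, 1, 0.5)
  expect_equal(predict(fit, matrix(c(0.3, -0.2), 1))$p_malignant,
               softmax2(c(dm, db))[1], tolerance = 1e-12)
})

test_that("identical class distributions leave LDA near chance", {
  withr::with_seed(31, X <- matrix(rnorm(60 * 6), 60, 6))
  d <- spectra(X, seq(1810, 1800, by = -2), rep(c("benign", "malignant"), 30))
  fit <- fit_lda(d)
  pr <- predict(fit, d)
  expect_lt(abs(mean(pr$p_malignant) - 0.5), 0.1)
})

test_that("SVM satisfies the KKT picture on the 1-D separable toy", {
  toy <- svm_toy()
  fit <- fit_svm(toy, learning_rate = 0.05, epochs = 500, seed = 1)
  y <- c(-1, -1, 1, 1)
  margins <- y * (fit$weights * c(-2, -1, 1, 2) + fit$bias)
  expect_true(all(margins >= 1 - 1e-3))            # feasible with unit margin
  expect_equal(sum(predict(fit, toy)$class != toy$labels), 0) # zero training error
  expect_equal(fit$alphas[c(1, 4)], c(0, 0))        # interior points inactive
  expect_true(all(fit$alphas[2:3] > 0.1))           # margin points support
  fit2 <- fit_svm(toy, learning_rate = 0.05, epochs = 500, seed = 1)
  expect_identical(fit$weights, fit2$weights)
})

test_that("Platt calibration recovers a known sigmoid and is monotone", {
  # replicated draws whose empirical frequencies match the sigmoid exactly
  truth <- c(a = -3, b = 0.5)
  f_grid <- seq(-2, 2, by = 0.2)
  p_true <- 1 / (1 + exp(truth["a"] * f_grid + truth["b"]))
  n_rep <- 400
  f <- rep(f_grid, each = n_rep)
  y <- unlist(lapply(p_true, function(p) {
    k <- round(n_rep * p)
    c(rep(TRUE, k), rep(FALSE, n_rep - k))
  }))
  est <- fit_platt(f, y)
  expect_equal(as.numeric(est["a"]), -3, tolerance = 0.05)
  expect_equal(as.numeric(est["b"]), 0.5, tolerance = 0.05)

  toy <- svm_toy()
  fit <- fit_svm(toy, learning_rate = 0.05, epochs = 300, seed = 1)
  fit$platt_b <- 0
  grid <- spectra(matrix(seq(-3, 3, by = 0.5), ncol = 1), 1000,
                  rep("benign", 13))
  pr <- predict(fit, grid)$p_malignant
  expect_true(all(diff(pr) > 0)) # platt_a < 0 so p increases with f
  x0 <- -fit$bias / fit$weights  # decision value exactly 0
  expect_equal(predict(fit, x0)$p_malignant, 0.5, tolerance = 1e-9)
  fit$platt_a <- NA_real_
  expect_error(predict(fit, grid), "Platt")
})

test_that("logistic regression behaves like its closed form", {
  toy <- svm_toy()
  null_fit <- fit_logreg(toy, epochs = 0)
  expect_equal(predict(null_fit, toy)$p_malignant, rep(0.5, 4))

  fit <- fit_logreg(toy, learning_rate = 0.5, epochs = 50, seed = 2)
  expect_equal(sum(predict(fit, toy)$class != toy$labels), 0)
  # |w| grows monotonically with epochs on separable data
  norms <- vapply(c(10, 40, 160), function(ep) {
    abs(fit_logreg(toy, learning_rate = 0.5, epochs = ep, seed = 2)$weights)
  }, numeric(1))
  expect_true(all(diff(norms) > 0))
  # saturation in the bias
  sat <- fit
  sat$bias <- 1000
  expect_equal(predict(sat, toy)$p_malignant, rep(1, 4), tolerance = 1e-9)
})

test_that("gini_best_split matches the worked example and brute force", {
  s <- gini_best_split(c(1, 2, 3, 10, 11, 12),
                       c("benign", "benign", "benign",
                         "malignant", "malignant", "malignant"))
  expect_equal(s$threshold, 6.5)
  expect_equal(s$score, 0)
  expect_null(gini_best_split(c(1, 2, 3), rep("benign", 3)))
  expect_null(gini_best_split(c(2, 2, 2), c("benign", "malignant", "benign")))

  brute <- function(v, lab) {
    mal <- lab == "malignant"
    cand <- sort(unique(v))
    thr <- (head(cand, -1) + tail(cand, -1)) / 2
    imp <- vapply(thr, function(t) {
      l <- v <= t
      gini <- function(m) {
        if (length(m) == 0) return(0)
        p <- mean(m); 1 - p^2 - (1 - p)^2
      }
      mean(l) * gini(mal[l]) + mean(!l) * gini(mal[!l])
    }, numeric(1))
    list(threshold = thr[which.min(imp)], score = min(imp))
  }
  for (k in 1:50) {
    withr::with_seed(500 + k, {
      v <- sample(1:8, 12, replace = TRUE) + rnorm(12, sd = 0.01)
      lab <- sample(c("benign", "malignant"), 12, replace = TRUE)
    })
    if (length(unique(lab)) < 2) next
    got <- gini_best_split(v, lab)
    want <- brute(v, lab)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$score, want$score)
  }
})

test_that("trees match an independent recursive grower on a toy set", {
  # independent oracle: plain recursive splitter with the same impurity rule
  oracle_tree <- function(X, mal, depth) {
    if (depth == 0 || length(unique(mal)) < 2) return(list(p = mean(mal)))
    best <- NULL
    for (j in seq_len(ncol(X))) {
      v <- X[, j]
      cand <- sort(unique(v))
      if (length(cand) < 2) next
      for (t in (head(cand, -1) + tail(cand, -1)) / 2) {
        l <- v <= t
        gini <- function(m) { p <- mean(m); 1 - p^2 - (1 - p)^2 }
        sc <- mean(l) * gini(mal[l]) + mean(!l) * gini(mal[!l])
        if (is.null(best) || sc < best$sc - 1e-12) best <- list(j = j, t = t, sc = sc)
      }
    }
    if (is.null(best)) return(list(p = mean(mal)))
    l <- X[, best$j] <= best$t
    list(j = best$j, t = best$t,
         left = oracle_tree(X[l, , drop = FALSE], mal[l], depth - 1),
         right = oracle_tree(X[!l, , drop = FALSE], mal[!l], depth - 1))
  }
  oracle_prob <- function(node, x) {
    if (!is.null(node$p)) return(node$p)
    if (x[node$j] <= node$t) oracle_prob(node$left, x) else oracle_prob(node$right, x)
  }
  withr::with_seed(77, {
    X <- matrix(rnorm(40 * 3), 40, 3)
    mal <- as.integer(X[, 2] + 0.4 * X[, 3] + rnorm(40, sd = 0.4) > 0)
  })
  labs <- ifelse(mal == 1, "malignant", "benign")
  d <- spectra(X, c(1804, 1802, 1800), labs)
  fit <- grow_tree(d, d, max_depth = 2) # same data as validation: growth to cap
  ref <- oracle_tree(X, mal, 2)
  got <- predict(fit, d)$p_malignant
  want <- apply(X, 1, function(x) oracle_prob(ref, x))
  expect_equal(got, want)
})

test_that("tree growth stops at a pure node or by validation accuracy", {
  # perfectly separable single feature: depth-1 tree, perfect validation
  v <- c(1, 2, 3, 10, 11, 12)
  d <- spectra(cbind(v, 0.1), c(1802, 1800),
               rep(c("benign", "malignant"), each = 3))
  fit <- grow_tree(d, d)
  expect_equal(fit$depth, 1L)
  expect_equal(fit$val_accuracy, 1)
  pure <- spectra(cbind(v, 0.2), c(1802, 1800), rep("malignant", 6))
  leaf <- grow_tree(pure, d)
  expect_equal(leaf$depth, 0L)
  expect_equal(predict(leaf, d)$p_malignant, rep(1, 6))
})

test_that("a 1-tree forest reduces to its tree and forests are seeded", {
  d <- toy_spectra(n_per_class = 15, seed = 40)
  plan <- make_splits(d$labels, 1, 1, seed = 2)
  tr <- subset_samples(d, plan$train[[1]])
  va <- subset_samples(d, plan$val[[1]])
  f1 <- fit_rf(tr, va, n_trees = 1, seed = 9)
  expect_equal(predict(f1, d)$class,
               factor(ifelse(predict(f1$trees[[1]], d)$p_malignant > 0.5,
                             "malignant", "benign"),
                      levels = c("benign", "malignant")))
  f2 <- fit_rf(tr, va, n_trees = 5, seed = 9)
  f3 <- fit_rf(tr, va, n_trees = 5, seed = 9)
  expect_identical(predict(f2, d)$p_malignant, predict(f3, d)$p_malignant)
})

test_that("bagging does not hurt accuracy on noisy data (sign test)", {
  wins <- 0; total <- 0
  for (s in 1:6) {
    d <- toy_spectra(n_per_class = 30, gap = 1.2, noise = 0.8, seed = 600 + s)
    plan <- make_splits(d$labels, 1, 1, seed = s)
    tr <- subset_samples(d, plan$train[[1]])
    va <- subset_samples(d, plan$val[[1]])
    te <- subset_samples(d, plan$test[[1]])
    forest <- fit_rf(tr, va, n_trees = 10, seed = s)
    acc_f <- mean(predict(forest, te)$class == te$labels)
    acc_t <- mean(vapply(forest$trees, function(t) {
      mean((predict(t, te)$p_malignant > 0.5) == (te$labels == "malignant"))
    }, numeric(1)))
    wins <- wins + (acc_f >= acc_t); total <- total + 1
  }
  expect_gte(wins, total / 2)
})

test_that("forest size search scans the grid and returns the best size", {
  d <- toy_spectra(n_per_class = 12, seed = 41)
  plan <- make_splits(d$labels, 1, 1, seed = 3)
  res <- rf_size_search(subset_samples(d, plan$train[[1]]),
                        subset_samples(d, plan$val[[1]]),
                        sizes = c(3, 5), trials = 2, seed = 7)
  expect_equal(nrow(res$surface), 2)
  expect_true(res$best_n_trees %in% c(3, 5))
})

test_that("naive Bayes finds a separating feature and stays inside (0,1)", {
  withr::with_seed(55, {
    X <- matrix(rnorm(60 * 10), 60, 10)
    lab <- rep(c("benign", "malignant"), 30)
    X[, 4] <- ifelse(lab == "malignant", 3, -3) + rnorm(60, sd = 0.2)
  })
  d <- spectra(X, seq(1818, 1800, by = -2), lab)
  plan <- make_splits(d$labels, 1, 1, seed = 4)
  fit <- fit_nb(subset_samples(d, plan$train[[1]]),
                subset_samples(d, plan$val[[1]]))
  tr <- subset_samples(d, plan$train[[1]])
  pr <- predict(fit, tr)
  expect_true(all((pr$p_malignant > 0.5) == (tr$labels == "malignant")))
  expect_true(all(pr$p_malignant > 0 & pr$p_malignant < 1))
  expect_true(4 %in% fit$feature_order[seq_len(fit$n_features)])
})

test_that("uninformative features leave naive Bayes near the class prior", {
  withr::with_seed(56, X <- matrix(rnorm(90 * 6), 90, 6))
  lab <- rep(c("benign", "benign", "malignant"), 30) # prior 1/3 malignant
  d <- spectra(X, seq(1810, 1800, by = -2), lab)
  plan <- make_splits(d$labels, 1, 1, seed = 5)
  fit <- fit_nb(subset_samples(d, plan$train[[1]]),
                subset_samples(d, plan$val[[1]]))
  pr <- predict(fit, d)
  expect_lt(abs(mean(pr$p_malignant) - 1 / 3), 0.1)
})

test_that("all six models separate a common linearly separable dataset", {
  d <- simulate_dataset(100, 100, bands = separable_bands(2), seed = 99)
  p <- preprocess(d)
  plan <- make_splits(p$labels, 1, 1, seed = 6)
  tr <- subset_samples(p, plan$train[[1]])
  va <- subset_samples(p, plan$val[[1]])
  te <- subset_samples(p, plan$test[[1]])
  for (model in c("lda", "svm", "lr", "dt", "rf", "nb")) {
    fit <- spectrasense:::fit_classifier(classifier_spec(model), tr, va, seed = 8)
    pr <- predict(fit, te)
    expect_gte(mean(pr$class == te$labels), 0.9)
    expect_prob_pairs(pr)
  }
})
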