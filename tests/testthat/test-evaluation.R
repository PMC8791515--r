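test_that("split plans are stratified, disjoint, covering, and seeded", {
  labels <- rep(c("malignant", "benign"), c(88, 78))
  plan <- make_splits(labels, trials = 50, folds = 10, seed = 123)
  expect_equal(nrow(plan), 500)
  n_mal <- sum(labels == "malignant")
  for (i in seq_len(nrow(plan))) {
    tr <- plan$train[[i]]; va <- plan$val[[i]]; te <- plan$test[[i]]
    expect_equal(sort(c(tr, va, te)), seq_along(labels))
    expect_equal(length(intersect(tr, va)), 0)
    expect_equal(length(intersect(tr, te)), 0)
    expect_equal(length(te), 25, tolerance = 1)
    mal_te <- sum(labels[te] == "malignant")
    expect_lt(abs(mal_te - length(te) * n_mal / 166), 1)
  }
  plan2 <- make_splits(labels, trials = 50, folds = 10, seed = 123)
  expect_identical(plan$train, plan2$train)
  expect_error(make_splits(labels, fractions = c(0.7, 0.2, 0.2)), "sum to 1")
})

test_that("metrics match hand confusion-matrix arithmetic", {
  perfect <- compute_metrics(rep(c("malignant", "benign"), each = 5),
                             c(rep(0.9, 5), rep(0.1, 5)))
  expect_equal(unlist(perfect), rep(1, 6), ignore_attr = TRUE)

  # TP = 9, FN = 1, TN = 8, FP = 2
  truth <- rep(c("malignant", "benign"), each = 10)
  prob <- c(rep(0.9, 9), 0.1, rep(0.1, 8), rep(0.9, 2))
  m <- compute_metrics(truth, prob)
  expect_equal(m$acc, 0.85)
  expect_equal(m$ppv, 9 / 11)
  expect_equal(m$npv, 8 / 9)
  expect_equal(m$sr, 0.8)
  expect_equal(m$rr, 0.9)

  flat <- compute_metrics(truth, rep(0.4, 20))
  expect_equal(flat$auc, 0.5)
  expect_true(is.na(flat$ppv)) # nothing called malignant
  expect_error(compute_metrics(rep("benign", 5), runif(5)), "single-class")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(21, {
    truth <- sample(c("malignant", "benign"), 40, replace = TRUE)
    score <- runif(40)
  })
  a1 <- compute_metrics(truth, score)$auc
  a2 <- compute_metrics(truth, plogis(5 * score - 2))$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  # and equals the rank-based (Mann-Whitney) formula
  pos <- truth == "malignant"
  u <- mann_whitney_u(score[pos], score[!pos])$statistic
  expect_equal(a1, u / (sum(pos) * sum(!pos)), tolerance = 1e-12)
})

test_that("aggregation follows the trial-then-fold mean and SD definitions", {
  grid <- tidyr::expand_grid(trial = 1:2, fold = 1:2)
  vals <- tibble::tibble(trial = grid$trial, fold = grid$fold,
                         metric = "acc", value = c(1, 0, 1, 1))
  out <- aggregate_metrics(vals)
  expect_equal(out$mean, mean(c(mean(c(1, 0)), mean(c(1, 1)))))
  expect_equal(out$mean, 0.75)
  expect_equal(out$sd, mean(c(sd(c(1, 0)), sd(c(1, 1)))))
  expect_equal(out$sd, (sqrt(0.5) + 0) / 2, tolerance = 1e-12)

  const <- tibble::tibble(trial = rep(1:3, each = 4), fold = rep(1:4, 3),
                          metric = "auc", value = 0.9)
  agg <- aggregate_metrics(const)
  expect_equal(agg$mean, 0.9)
  expect_equal(agg$sd, 0)

  # complete grid: trial-mean-of-fold-means equals the grand mean
  withr::with_seed(22, big <- tibble::tibble(
    trial = rep(1:6, each = 5), fold = rep(1:5, 6),
    metric = "rr", value = runif(30)))
  expect_equal(aggregate_metrics(big)$mean, mean(big$value), tolerance = 1e-12)
  expect_error(aggregate_metrics(big[0, ]), "no metric values")
})

test_that("Mann-Whitney U equals brute-force pair counting, exact and approximate", {
  brute_u <- function(a, b) {
    sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
  }
  for (na in 2:6) for (nb in 2:6) {
    withr::with_seed(na * 10 + nb, {
      a <- sample(1:5, na, replace = TRUE) + 0.1
      b <- sample(1:5, nb, replace = TRUE)
    })
    got <- mann_whitney_u(a, b)
    expect_equal(got$statistic, brute_u(a, b))
    expect_gte(got$p_value, 0)
    expect_lte(got$p_value, 1)
  }
  # exact two-sided p agrees with the reference implementation without ties
  withr::with_seed(9, { a <- rnorm(6); b <- rnorm(5) + 1 })
  expect_equal(mann_whitney_u(a, b)$p_value,
               wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  # normal approximation agrees with the reference on larger samples
  withr::with_seed(10, { a <- rnorm(30); b <- rnorm(25) + 0.5 })
  expect_equal(mann_whitney_u(a, b)$p_value,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-6)
})

test_that("model comparison reports mean differences and p-values", {
  same <- compare_models(rep(0.9, 10), rep(0.9, 10), metric = "acc")
  expect_equal(same$mean_difference, 0)
  expect_gt(same$p_value, 0.9)
  withr::with_seed(12, {
    hi <- runif(10, 0.8, 0.9)
    lo <- runif(10, 0.1, 0.2)
  })
  apart <- compare_models(hi, lo)
  expect_lt(apart$p_value, 0.001)
  expect_gt(apart$mean_difference, 0.5)
  expect_error(compare_models(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("peak table controls type-I error and detects planted shifts", {
  grid <- seq(1470, 1430, by = -2)
  gauss <- exp(-(grid - 1452)^2 / (2 * 8^2))
  sig <- 0; null <- 0
  for (k in 1:100) {
    withr::with_seed(3000 + k, {
      amp_b <- rnorm(40, 1, 0.3)
      amp_m_null <- rnorm(40, 1, 0.3)
      amp_m_shift <- rnorm(40, 1 + 1.5 * 0.3, 0.3)
    })
    mk <- function(amp_m) {
      spectra(rbind(outer(amp_m, gauss), outer(amp_b, gauss)) +
                matrix(rnorm(80 * length(grid), sd = 0.01), 80),
              grid, rep(c("malignant", "benign"), each = 40))
    }
    null <- null + peak_table(mk(amp_m_null), 1452)$significant
    sig <- sig + peak_table(mk(amp_m_shift), 1452)$significant
  }
  expect_lte(null, 10)  # about the nominal 5% false-positive rate
  expect_gte(sig, 90)   # 1.5 SD shift at n = 40/40 is nearly always seen
})

test_that("peak table reports one row per requested position", {
  d <- simulate_dataset(20, 20, seed = 17)
  tab <- peak_table(d, c(1452, 1236, 1032))
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$mann_whitney_p >= 0 & tab$mann_whitney_p <= 1))
  tab2 <- peak_table(d, list(malignant = c(1632, 1032), benign = c(1634, 1030)))
  expect_equal(nrow(tab2), 2)
  expect_error(peak_table(d, 4000), "off the grid")
})

test_that("peak finding locates prominent local maxima only", {
  grid <- seq(1800, 850, by = -2)
  one <- exp(-(grid - 1452)^2 / (2 * 8^2))
  got <- find_peaks(one, grid, min_prominence = 0.5)
  expect_length(got, 1)
  expect_lte(abs(got - 1452), 2)
  expect_length(find_peaks(seq_along(grid) * 0.01, grid, 0.001), 0)
  two <- one + 0.8 * exp(-(grid - 1236)^2 / (2 * 8^2))
  got2 <- find_peaks(two, grid, min_prominence = 0.3)
  expect_length(got2, 2)
  expect_equal(got2, sort(got2, decreasing = TRUE))
  expect_true(any(abs(got2 - 1452) <= 2) && any(abs(got2 - 1236) <= 2))
})

test_that("the evaluation pipeline yields tidy metrics and summaries", {
  d <- toy_spectra(n_per_class = 20, seed = 50)
  m <- evaluate_classifiers(d, list(lda = classifier_spec("lda"),
                                    dt = classifier_spec("dt")),
                            trials = 2, folds = 2, seed = 3)
  expect_setequal(unique(m$model), c("lda", "dt"))
  expect_equal(nrow(m), 2 * 2 * 2 * 6)
  expect_setequal(unique(m$metric), c("auc", "acc", "ppv", "npv", "sr", "rr"))
  s <- summarize_models(m)
  expect_equal(nrow(s), 12)
  cmp <- compare_to_reference(m, "lda")
  expect_equal(nrow(cmp), 6)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_s3_class(autoplot(m), "ggplot")
})
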