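#' Stratified Monte-Carlo train/validation/test split plan
#'
#' Builds `trials x folds` independent random resamples of the sample
#' indices into train/validation/test sets at the given fractions
#' (default 70/15/15). Within every split the class proportions are
#' preserved to within one sample (per-class largest-remainder allocation),
#' the three sets are disjoint, and their union is the full index set.
#' This is repeated random resampling, not a partition-based k-fold: every
#' fold is redrawn independently.
#'
#' @param labels Class label vector (benign/malignant).
#' @param trials Number of trials T.
#' @param folds Resamples per trial.
#' @param fractions Train/validation/test fractions, summing to 1.
#' @param seed Integer seed; the full plan is deterministic given it.
#' @return A tibble of class `split_plan` with columns `trial`, `fold`, and
#'   list-columns `train`, `val`, `test` holding integer index vectors.
#' @export
make_splits <- function(labels, trials = 50, folds = 10,
                        fractions = c(0.70, 0.15, 0.15), seed = 1) {
  labels <- normalize_labels(labels)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  if (length(fractions) != 3 || any(fractions <= 0)) {
    stop("need three positive fractions (train, validation, test)", call. = FALSE)
  }
  class_idx <- split(seq_along(labels), labels)
  plan <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(trials), function(t) {
      purrr::map_dfr(seq_len(folds), function(n) {
        sets <- list(train = integer(), val = integer(), test = integer())
        for (idx in class_idx) {
          k <- largest_remainder(length(idx), fractions)
          perm <- sample(idx)
          sets$train <- c(sets$train, perm[seq_len(k[1])])
          sets$val <- c(sets$val, perm[k[1] + seq_len(k[2])])
          sets$test <- c(sets$test, perm[k[1] + k[2] + seq_len(k[3])])
        }
        tibble::tibble(trial = t, fold = n,
                       train = list(sort(sets$train)),
                       val = list(sort(sets$val)),
                       test = list(sort(sets$test)))
      })
    })
  })
  class(plan) <- c("split_plan", class(plan))
  plan
}

# integer allocation of n into parts proportional to fractions
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  k <- floor(raw)
  left <- n - sum(k)
  if (left > 0) {
    extra <- order(raw - k, decreasing = TRUE)[seq_len(left)]
    k[extra] <- k[extra] + 1
  }
  as.integer(k)
}

#' Six diagnostic metrics from probabilities
#'
#' Confusion-matrix metrics at a fixed threshold on the malignant
#' probability (malignant is the positive class), plus the trapezoidal area
#' under the ROC curve over all distinct score thresholds. Metrics with a
#' zero denominator are returned as `NA` ("undefined") and later excluded
#' pairwise by [aggregate_metrics()].
#'
#' @param truth Class labels (benign/malignant).
#' @param prob_malignant Predicted malignant probabilities.
#' @param threshold Classification threshold (default 0.5; malignant when
#'   strictly above).
#' @return A one-row tibble with `auc`, `acc`, `ppv`, `npv`, `sr`, `rr`.
#' @export
compute_metrics <- function(truth, prob_malignant, threshold = 0.5) {
  truth <- normalize_labels(truth)
  stopifnot(length(truth) == length(prob_malignant))
  if (length(unique(truth)) < 2) {
    stop("AUC is undefined for single-class truth", call. = FALSE)
  }
  pos <- truth == "malignant"
  pred <- prob_malignant > threshold
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  tn <- sum(!pred & !pos); fn <- sum(!pred & pos)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    auc = roc_auc(pos, prob_malignant),
    acc = (tp + tn) / length(truth),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    sr = safe_div(tn, tn + fp),
    rr = safe_div(tp, tp + fn)
  )
}

# trapezoidal AUC over the ROC swept across all distinct score thresholds
roc_auc <- function(pos, score) {
  thr <- sort(unique(score), decreasing = TRUE)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  tpr <- c(0, vapply(thr, function(t) sum(score >= t & pos), numeric(1)) / n_pos)
  fpr <- c(0, vapply(thr, function(t) sum(score >= t & !pos), numeric(1)) / n_neg)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Aggregate per-(trial, fold) metric values
#'
#' The overall mean of a metric is the mean over trials of its per-trial
#' fold-means; the overall SD is the mean over trials of the per-trial fold
#' sample SDs. On a complete grid the overall mean equals the grand mean.
#' Undefined (`NA`) entries are excluded pairwise and counted.
#'
#' @param values A tibble with columns `trial`, `fold`, `metric`, `value`
#'   (e.g. from [evaluate_classifiers()]).
#' @return A tibble with one row per metric: `mean`, `sd`, `n_undefined`.
#' @export
aggregate_metrics <- function(values) {
  stopifnot(all(c("trial", "fold", "metric", "value") %in% names(values)))
  if (nrow(values) == 0) stop("no metric values to aggregate", call. = FALSE)
  values |>
    dplyr::group_by(.data$metric, .data$trial) |>
    dplyr::summarise(
      fold_mean = mean(.data$value, na.rm = TRUE),
      fold_sd = stats::sd(.data$value[!is.na(.data$value)]),
      n_na = sum(is.na(.data$value)),
      .groups = "drop_last"
    ) |>
    dplyr::summarise(
      mean = mean(.data$fold_mean, na.rm = TRUE),
      sd = mean(.data$fold_sd, na.rm = TRUE),
      n_undefined = sum(.data$n_na),
      .groups = "drop"
    )
}

#' Mann-Whitney U test (two-sided)
#'
#' The U statistic counts pairs where an `a` value exceeds a `b` value, ties
#' counting one half. The p-value uses exact enumeration of the permutation
#' distribution when both samples have at most `exact_max` observations, and
#' the tie-corrected normal approximation (with continuity correction)
#' otherwise.
#'
#' @param a,b Numeric samples.
#' @param exact_max Size bound below which the exact distribution is used.
#' @return A list with `statistic` (U for sample `a`) and `p_value`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 8) {
  n_a <- length(a); n_b <- length(b)
  stopifnot(n_a >= 1, n_b >= 1)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  if (n_a <= exact_max && n_b <= exact_max) {
    combos <- utils::combn(n_a + n_b, n_a)
    us <- apply(combos, 2, function(ix) sum(r[ix]) - n_a * (n_a + 1) / 2)
    p <- 2 * min(mean(us <= u_a + 1e-9), mean(us >= u_a - 1e-9))
  } else {
    mu <- n_a * n_b / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / ((n_a + n_b) * (n_a + n_b - 1))
    sigma2 <- n_a * n_b / 12 * ((n_a + n_b + 1) - tie_term)
    if (sigma2 <= 0) return(list(statistic = u_a, p_value = 1))
    z <- (u_a - mu - sign(u_a - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = u_a, p_value = min(p, 1))
}

#' Compare two models' per-split metric values
#'
#' Reports the difference of overall means (`a - b`) and the two-sided
#' Mann-Whitney p-value over the paired collections of per-(trial, fold)
#' values.
#'
#' @param values_a,values_b Numeric vectors of per-split metric values
#'   (NA entries dropped).
#' @param metric Optional metric name carried into the output.
#' @return A one-row tibble: `metric`, `mean_difference`, `statistic`,
#'   `p_value`.
#' @export
compare_models <- function(values_a, values_b, metric = NA_character_) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 3 || length(values_b) < 3) {
    stop("need at least 3 values per side", call. = FALSE)
  }
  mw <- mann_whitney_u(values_a, values_b)
  tibble::tibble(
    metric = metric,
    mean_difference = mean(values_a) - mean(values_b),
    statistic = mw$statistic,
    p_value = mw$p_value
  )
}

#' Per-peak class comparison table
#'
#' For each nominal peak position, the per-sample peak absorbance is the
#' local maximum within +/- `window` cm^-1 of the position. Per class the
#' mean, SD and Shapiro-Wilk normality p-value are reported, together with
#' the two-sided Mann-Whitney p-value between classes and a significance
#' flag at `alpha`.
#'
#' @param x A [spectra] object containing both classes.
#' @param positions Numeric vector of shared peak positions (cm^-1), or a
#'   named list `list(malignant = ..., benign = ...)` of per-class positions
#'   (same length).
#' @param window Half-width of the search window in cm^-1 (default 8).
#' @param alpha Significance level (default 0.05).
#' @return A tibble with one row per position.
#' @export
peak_table <- function(x, positions, window = 8, alpha = 0.05) {
  stopifnot(inherits(x, "spectra"))
  if (length(unique(x$labels)) < 2) stop("need both classes", call. = FALSE)
  if (is.list(positions)) {
    pos_m <- positions$malignant
    pos_b <- positions$benign
    stopifnot(length(pos_m) == length(pos_b))
  } else {
    pos_m <- pos_b <- positions
  }
  peak_values <- function(subset, pos) {
    sel <- abs(x$wavenumber - pos) <= window
    if (!any(sel)) stop("position ", pos, " cm^-1 is off the grid", call. = FALSE)
    apply(subset$absorbance[, sel, drop = FALSE], 1, max)
  }
  mal <- class_subset(x, "malignant")
  ben <- class_subset(x, "benign")
  purrr::map_dfr(seq_along(pos_m), function(i) {
    vm <- peak_values(mal, pos_m[i])
    vb <- peak_values(ben, pos_b[i])
    sw <- function(v) {
      if (length(unique(v)) < 3) return(NA_real_)
      stats::shapiro.test(v)$p.value
    }
    mw <- mann_whitney_u(vm, vb)
    tibble::tibble(
      position_malignant = pos_m[i], position_benign = pos_b[i],
      mean_malignant = mean(vm), sd_malignant = stats::sd(vm),
      mean_benign = mean(vb), sd_benign = stats::sd(vb),
      shapiro_p_malignant = sw(vm), shapiro_p_benign = sw(vb),
      mann_whitney_p = mw$p_value,
      significant = mw$p_value < alpha
    )
  })
}

#' Locate peaks in a single spectrum
#'
#' Local maxima whose prominence (height above the higher of the two
#' flanking minima, searched until a higher point or the spectrum edge) is
#' at least `min_prominence`.
#'
#' @param values Absorbance vector.
#' @param wavenumber Matching wavenumber vector.
#' @param min_prominence Minimum prominence in absorbance units.
#' @return Numeric vector of peak positions (cm^-1), sorted by descending
#'   wavenumber.
#' @export
find_peaks <- function(values, wavenumber, min_prominence = 0) {
  L <- length(values)
  stopifnot(length(wavenumber) == L, L >= 3)
  mid <- 2:(L - 1)
  is_peak <- mid[values[mid] > values[mid - 1] & values[mid] > values[mid + 1]]
  keep <- vapply(is_peak, function(i) {
    h <- values[i]
    base_side <- function(idx_range) {
      if (length(idx_range) == 0) return(min(h, values[i]))
      lo <- Inf
      for (j in idx_range) {
        if (values[j] > h) break
        lo <- min(lo, values[j])
      }
      if (is.infinite(lo)) h else lo
    }
    left <- base_side(rev(seq_len(i - 1)))
    right <- base_side(seq(i + 1, L))
    h - max(left, right) >= min_prominence
  }, logical(1))
  pos <- wavenumber[is_peak[keep]]
  sort(pos, decreasing = TRUE)
}

# ---- end-to-end model evaluation -------------------------------------------

#' Classifier specification for the evaluation pipeline
#'
#' A lightweight description of one model to be fitted on each Monte-Carlo
#' split: its type and hyperparameters.
#'
#' @param model One of `"fnn"`, `"lda"`, `"svm"`, `"lr"`, `"dt"`, `"rf"`,
#'   `"nb"`.
#' @param ... Hyperparameters forwarded to the matching fit function
#'   (e.g. `width`, `epochs`, `learning_rate` for `"fnn"`; `n_trees` for
#'   `"rf"`).
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(model = c("fnn", "lda", "svm", "lr", "dt", "rf", "nb"),
                            ...) {
  model <- match.arg(model)
  structure(list(model = model, args = list(...)), class = "classifier_spec")
}

fit_classifier <- function(spec, train, val, seed) {
  a <- spec$args
  switch(spec$model,
    fnn = {
      cfg <- do.call(fnn_config, c(a, list(seed = seed)))
      train_fnn(train, val, cfg)
    },
    lda = do.call(fit_lda, c(list(train), a)),
    svm = do.call(fit_svm, c(list(train, val), a, list(seed = seed))),
    lr = do.call(fit_logreg, c(list(train), a, list(seed = seed))),
    dt = do.call(grow_tree, c(list(train, val), a)),
    rf = do.call(fit_rf, c(list(train, val), a, list(seed = seed))),
    nb = do.call(fit_nb, c(list(train, val), a))
  )
}

#' Evaluate classifiers over a Monte-Carlo cross-validation plan
#'
#' For every (trial, fold) split each classifier is fitted on the training
#' portion (with the validation portion available to the models that use
#' one), its malignant probabilities are computed on the test portion, and
#' the six diagnostic metrics are recorded.
#'
#' @param x A preprocessed [spectra] object.
#' @param specs A named list of [classifier_spec()]s.
#' @param trials,folds,fractions,seed Split plan passed to [make_splits()].
#' @return A tibble of class `model_metrics`: `model`, `trial`, `fold`,
#'   `metric`, `value` (tidy long format).
#' @export
evaluate_classifiers <- function(x, specs, trials = 5, folds = 3,
                                 fractions = c(0.70, 0.15, 0.15), seed = 1) {
  stopifnot(inherits(x, "spectra"))
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  if (is.null(names(specs)) || any(names(specs) == "")) {
    names(specs) <- vapply(specs, `[[`, character(1), "model")
  }
  splits <- make_splits(x$labels, trials, folds, fractions, seed)
  out <- purrr::map_dfr(names(specs), function(nm) {
    purrr::map_dfr(seq_len(nrow(splits)), function(i) {
      train <- subset_samples(x, splits$train[[i]])
      val <- subset_samples(x, splits$val[[i]])
      test <- subset_samples(x, splits$test[[i]])
      fit <- fit_classifier(specs[[nm]], train, val, seed = seed + 7919L * i)
      m <- compute_metrics(test$labels, predict(fit, test)$p_malignant)
      tidyr::pivot_longer(m, dplyr::everything(),
                          names_to = "metric", values_to = "value") |>
        tibble::add_column(model = nm, trial = splits$trial[i],
                           fold = splits$fold[i], .before = 1)
    })
  })
  class(out) <- c("model_metrics", class(out))
  out
}

#' Summary table of model performance
#'
#' Mean and SD of every metric per model, via [aggregate_metrics()].
#'
#' @param x A `model_metrics` tibble from [evaluate_classifiers()].
#' @param ... Unused.
#' @return Tibble with `model`, `metric`, `mean`, `sd`, `n_undefined`.
#' @export
summarize_models <- function(x, ...) {
  x |>
    dplyr::group_by(.data$model) |>
    dplyr::group_modify(~aggregate_metrics(.x)) |>
    dplyr::ungroup()
}

#' Pairwise model comparison against a reference model
#'
#' For each metric, the difference of overall means (model minus reference)
#' and the two-sided Mann-Whitney p-value over the per-(trial, fold) values.
#'
#' @param x A `model_metrics` tibble.
#' @param reference Name of the reference model.
#' @return Tibble with `model`, `metric`, `mean_difference`, `p_value`.
#' @export
compare_to_reference <- function(x, reference) {
  stopifnot(reference %in% x$model)
  ref <- dplyr::filter(x, .data$model == reference)
  x |>
    dplyr::filter(.data$model != reference) |>
    dplyr::group_by(.data$model, .data$metric) |>
    dplyr::group_modify(function(d, key) {
      r <- ref$value[ref$metric == key$metric]
      compare_models(d$value, r)[, c("mean_difference", "statistic", "p_value")]
    }) |>
    dplyr::ungroup()
}

#' Metric distributions across splits
#' @param object A `model_metrics` tibble.
#' @param ... Unused.
#' @return A ggplot box plot of metric values per model.
#' @export
autoplot.model_metrics <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$model, y = .data$value,
                                       fill = .data$model)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "metric value") +
    ggplot2::theme_minimal()
}
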