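#' Naive Bayes on Gini-binarized features
#'
#' Every channel is binarized at its best Gini split threshold
#' ([gini_best_split()]). Channels are then considered in ascending order of
#' split impurity; starting from the 3 least-impure channels, features are
#' added one at a time and the validation accuracy is tracked, stopping as
#' soon as it decreases; the feature count with the highest validation
#' accuracy wins. Conditional tables use add-one (Laplace) smoothing, so all
#' probabilities are strictly inside (0, 1).
#'
#' By default the prediction is the smoothed class posterior (priors
#' included). `literal = TRUE` switches the prediction to the prior-free
#' ratio `prod_j P(m_j | malignant) / prod_j P(m_j)`, kept as a documented
#' option; it is not a calibrated probability.
#'
#' @param train A [spectra] object with both classes.
#' @param val A [spectra] validation set for the feature-count search.
#' @param literal Use the literal ratio form at prediction time?
#' @return An object of class `ftir_nb`.
#' @export
fit_nb <- function(train, val, literal = FALSE) {
  stopifnot(inherits(train, "spectra"), inherits(val, "spectra"))
  if (length(unique(train$labels)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  check_grid(train$wavenumber, val$wavenumber)
  X <- train$absorbance
  splits <- lapply(seq_len(ncol(X)), function(j) gini_best_split(X[, j], train$labels))
  usable <- which(!vapply(splits, is.null, logical(1)))
  if (length(usable) < 3) stop("need at least 3 splittable features", call. = FALSE)
  impurity <- vapply(splits[usable], `[[`, numeric(1), "score")
  feature_order <- usable[order(impurity)]
  thresholds <- vapply(splits[feature_order], `[[`, numeric(1), "threshold")

  is_mal <- train$labels == "malignant"
  bins <- sweep(X[, feature_order, drop = FALSE], 2, thresholds, `>`)
  # P(bin = TRUE | class) with add-one smoothing
  p_true_mal <- (colSums(bins[is_mal, , drop = FALSE]) + 1) / (sum(is_mal) + 2)
  p_true_ben <- (colSums(bins[!is_mal, , drop = FALSE]) + 1) / (sum(!is_mal) + 2)
  p_true_all <- (colSums(bins) + 1) / (nrow(bins) + 2)
  prior_mal <- mean(is_mal)

  model_n <- function(n) {
    structure(
      list(feature_order = feature_order[seq_len(n)],
           thresholds = thresholds[seq_len(n)],
           p_true_malignant = p_true_mal[seq_len(n)],
           p_true_benign = p_true_ben[seq_len(n)],
           p_true_marginal = p_true_all[seq_len(n)],
           n_features = n, class_prior_malignant = prior_mal,
           literal = literal, wavenumber = train$wavenumber),
      class = "ftir_nb"
    )
  }
  acc <- function(m) mean(predict(m, val)$class == val$labels)
  best_n <- 3
  best_acc <- acc(model_n(3))
  prev_acc <- best_acc
  n <- 3
  while (n < length(feature_order)) {
    n <- n + 1
    a <- acc(model_n(n))
    if (a > best_acc) { best_acc <- a; best_n <- n }
    if (a < prev_acc) break
    prev_acc <- a
  }
  m <- model_n(best_n)
  m$val_accuracy <- best_acc
  m
}

#' @export
print.ftir_nb <- function(x, ...) {
  cat(sprintf("<ftir_nb> %d binarized features, validation accuracy %.3f\n",
              x$n_features, x$val_accuracy %||% NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname fit_nb
#' @param object A fitted `ftir_nb`.
#' @param newdata A [spectra] object or matrix on the training grid.
#' @param ... Unused.
#' @return For `predict`: tibble with `p_benign`, `p_malignant`, `class`
#'   (malignant when the predictive value exceeds 0.5). In literal mode
#'   `p_malignant` is the uncalibrated Eq-style ratio.
#' @export
predict.ftir_nb <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectra")) {
    check_grid(object$wavenumber, newdata$wavenumber)
    newdata$absorbance
  } else if (is.vector(newdata)) matrix(newdata, nrow = 1) else as.matrix(newdata)
  bins <- sweep(X[, object$feature_order, drop = FALSE], 2, object$thresholds, `>`)
  loglik <- function(p_true) {
    # sum_j log P(m_j | class) for the observed bins
    bins %*% log(p_true) + (!bins) %*% log(1 - p_true)
  }
  ll_mal <- drop(loglik(object$p_true_malignant))
  ll_ben <- drop(loglik(object$p_true_benign))
  if (object$literal) {
    ll_marg <- drop(loglik(object$p_true_marginal))
    p_mal <- exp(ll_mal - ll_marg)
  } else {
    zm <- log(object$class_prior_malignant) + ll_mal
    zb <- log(1 - object$class_prior_malignant) + ll_ben
    p_mal <- 1 / (1 + exp(pmin(pmax(zb - zm, -500), 500)))
  }
  prob_tibble(cbind(1 - p_mal, p_mal),
              if (inherits(newdata, "spectra")) newdata$ids else NULL)
}
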