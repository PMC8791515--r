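#' Logistic regression trained by per-sample stochastic gradient descent
#'
#' Minimises the binary cross-entropy of
#' `p(x) = exp(b + w . x) / (1 + exp(b + w . x))` (malignant = 1) with plain
#' per-sample SGD in a seeded random order. The sigmoid is evaluated
#' overflow-safely.
#'
#' @param train A [spectra] object with both classes.
#' @param learning_rate Step size.
#' @param epochs Passes over the training set.
#' @param seed Integer seed for the visit order.
#' @return An object of class `ftir_lr` with `weights` and `bias`.
#' @export
fit_logreg <- function(train, learning_rate = 0.01, epochs = 200, seed = 1) {
  stopifnot(inherits(train, "spectra"))
  if (length(unique(train$labels)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  X <- train$absorbance
  y <- as.numeric(train$labels == "malignant")
  w <- numeric(ncol(X))
  b <- 0
  withr::with_seed(seed, {
    for (e in seq_len(epochs)) {
      for (i in sample.int(nrow(X))) {
        p <- sigmoid(b + sum(w * X[i, ]))
        err <- p - y[i]
        w <- w - learning_rate * err * X[i, ]
        b <- b - learning_rate * err
      }
      if (!all(is.finite(w)) || !is.finite(b)) {
        stop("logistic regression diverged at learning rate ", learning_rate,
             call. = FALSE)
      }
    }
  })
  structure(
    list(weights = w, bias = b, wavenumber = train$wavenumber),
    class = "ftir_lr"
  )
}

sigmoid <- function(z) 1 / (1 + exp(pmin(pmax(-z, -500), 500)))

#' @export
print.ftir_lr <- function(x, ...) {
  cat(sprintf("<ftir_lr> |w| = %.4g, b = %.4g\n", sqrt(sum(x$weights^2)), x$bias))
  invisible(x)
}

#' @rdname fit_logreg
#' @param object A fitted `ftir_lr`.
#' @param newdata A [spectra] object, matrix, or single spectrum vector.
#' @param ... Unused.
#' @return For `predict`: tibble with `p_benign`, `p_malignant`, `class`.
#' @export
predict.ftir_lr <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectra")) {
    check_grid(object$wavenumber, newdata$wavenumber)
    newdata$absorbance
  } else if (is.vector(newdata)) matrix(newdata, nrow = 1) else as.matrix(newdata)
  p_mal <- sigmoid(object$bias + drop(X %*% object$weights))
  prob_tibble(cbind(1 - p_mal, p_mal),
              if (inherits(newdata, "spectra")) newdata$ids else NULL)
}
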