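#' Linear support vector machine trained by stochastic subgradient descent
#'
#' Optimises the unconstrained Lagrangian of the hard-margin linear SVM with
#' label coding benign = -1, malignant = +1. Each epoch visits the training
#' samples in a seeded random order and performs projected gradient
#' ascent/descent on the saddle problem: the multiplier of sample i moves by
#' `learning_rate * (1 - margin_i)` (its exact Lagrangian gradient, positive
#' for margin violators), clipped at 0, so satisfied samples decay toward 0;
#' the weight vector follows `dL/dw = w - sum(alpha_i y_i x_i)` and the bias
#' follows `dL/db = -sum(alpha_i y_i)`. Because saddle-point SGD orbits the
#' optimum, the returned parameters are the Polyak averages of the iterates
#' over the second half of training, which settle on the KKT point. Support
#' vectors are the samples with `alpha_i != 0`.
#'
#' A Platt sigmoid `p(f) = 1 / (1 + exp(a f + b))` is fitted afterwards on
#' the decision values of `val` (or of the training set when `val` is NULL)
#' by Newton iteration on the regularised Platt targets.
#'
#' @param train A [spectra] object with both classes.
#' @param val Optional [spectra] validation set for Platt calibration.
#' @param learning_rate Initial step size.
#' @param epochs Passes over the training set.
#' @param seed Integer seed for the visit order.
#' @return An object of class `ftir_svm` with `weights`, `bias`, `alphas`,
#'   `platt_a`, `platt_b`.
#' @export
fit_svm <- function(train, val = NULL, learning_rate = 0.01, epochs = 200,
                    seed = 1) {
  stopifnot(inherits(train, "spectra"))
  if (length(unique(train$labels)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  X <- train$absorbance
  y <- ifelse(train$labels == "malignant", 1, -1)
  n <- nrow(X)
  alpha <- numeric(n)
  w <- numeric(ncol(X))
  b <- 0
  s_w <- numeric(ncol(X)) # running sum alpha_i y_i x_i
  s_b <- 0                # running sum alpha_i y_i
  w_avg <- numeric(ncol(X)); b_avg <- 0; a_avg <- numeric(n); n_avg <- 0
  withr::with_seed(seed, {
    for (e in seq_len(epochs)) {
      lr <- learning_rate
      for (i in sample.int(n)) {
        margin <- y[i] * (sum(w * X[i, ]) + b)
        d_alpha <- max(-alpha[i], lr * (1 - margin)) # dL/dalpha_i = 1 - margin
        if (d_alpha != 0) {
          alpha[i] <- alpha[i] + d_alpha
          s_w <- s_w + d_alpha * y[i] * X[i, ]
          s_b <- s_b + d_alpha * y[i]
        }
        w <- w - lr * (w - s_w)   # dL/dw = w - sum alpha y x
        b <- b + lr * s_b         # dL/db = -sum alpha y
        if (!all(is.finite(w)) || !is.finite(b)) {
          stop("SVM diverged at learning rate ", learning_rate, call. = FALSE)
        }
      }
      if (e > epochs / 2) {
        w_avg <- w_avg + w; b_avg <- b_avg + b; a_avg <- a_avg + alpha
        n_avg <- n_avg + 1
      }
    }
  })
  if (n_avg > 0) {
    w <- w_avg / n_avg; b <- b_avg / n_avg; alpha <- a_avg / n_avg
  }
  model <- structure(
    list(weights = w, bias = b, alphas = alpha,
         platt_a = NA_real_, platt_b = NA_real_,
         wavenumber = train$wavenumber),
    class = "ftir_svm"
  )
  cal <- if (is.null(val)) train else val
  f <- decision_values(model, cal)
  platt <- fit_platt(f, cal$labels == "malignant")
  model$platt_a <- platt[1]
  model$platt_b <- platt[2]
  model
}

decision_values <- function(model, x) {
  X <- if (inherits(x, "spectra")) {
    check_grid(model$wavenumber, x$wavenumber)
    x$absorbance
  } else if (is.vector(x)) matrix(x, nrow = 1) else as.matrix(x)
  drop(X %*% model$weights) + model$bias
}

#' Platt sigmoid calibration
#'
#' Fits `p = 1 / (1 + exp(a f + b))` to decision values `f` and binary
#' outcomes by Newton iteration on the cross-entropy with Platt's smoothed
#' targets `(n_pos + 1) / (n_pos + 2)` and `1 / (n_neg + 2)`.
#'
#' @param f Numeric decision values.
#' @param positive Logical vector: TRUE for the positive (malignant) class.
#' @param max_iter,tol Newton iteration controls.
#' @return Numeric `c(a, b)`.
#' @export
fit_platt <- function(f, positive, max_iter = 100, tol = 1e-10) {
  stopifnot(length(f) == length(positive))
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  t <- ifelse(positive, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  a <- 0
  b <- log((n_neg + 1) / (n_pos + 1))
  obj <- function(a, b) {
    z <- a * f + b
    # -sum(t log p + (1-t) log(1-p)), p = 1/(1+exp(z)); stable form
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  val <- obj(a, b)
  for (it in seq_len(max_iter)) {
    p <- 1 / (1 + exp(pmin(pmax(a * f + b, -500), 500)))
    d1 <- t - p          # d obj / dz for p = 1 / (1 + exp(z))
    g <- c(sum(d1 * f), sum(d1))
    wdiag <- pmax(p * (1 - p), 1e-12)
    h11 <- sum(wdiag * f * f) + 1e-12
    h12 <- sum(wdiag * f)
    h22 <- sum(wdiag) + 1e-12
    det <- h11 * h22 - h12^2
    step <- c(h22 * g[1] - h12 * g[2], -h12 * g[1] + h11 * g[2]) / det
    stepsize <- 1
    repeat {
      a_new <- a - stepsize * step[1]
      b_new <- b - stepsize * step[2]
      v_new <- obj(a_new, b_new)
      if (v_new < val + 1e-12 || stepsize < 1e-10) break
      stepsize <- stepsize / 2
    }
    if (abs(val - v_new) < tol) { a <- a_new; b <- b_new; break }
    a <- a_new; b <- b_new; val <- v_new
  }
  c(a = a, b = b)
}

#' @export
print.ftir_svm <- function(x, ...) {
  cat(sprintf("<ftir_svm> %d support vectors, |w| = %.4g, Platt (a, b) = (%.3g, %.3g)\n",
              sum(x$alphas != 0), sqrt(sum(x$weights^2)), x$platt_a, x$platt_b))
  invisible(x)
}

#' Predict malignancy probabilities from a fitted SVM
#'
#' The decision value `f = w . x + b` is mapped through the fitted Platt
#' sigmoid `p_malignant = 1 / (1 + exp(a f + b))`.
#'
#' @param object A fitted `ftir_svm`.
#' @param newdata A [spectra] object, matrix or single spectrum vector.
#' @param ... Unused.
#' @return Tibble with `p_benign`, `p_malignant`, `class`.
#' @export
predict.ftir_svm <- function(object, newdata, ...) {
  if (!is.finite(object$platt_a)) stop("Platt calibration has not been fitted", call. = FALSE)
  f <- decision_values(object, newdata)
  z <- pmin(pmax(object$platt_a * f + object$platt_b, -500), 500)
  p_mal <- 1 / (1 + exp(z))
  prob_tibble(cbind(1 - p_mal, p_mal),
              if (inherits(newdata, "spectra")) newdata$ids else NULL)
}
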