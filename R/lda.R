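#' Fisher linear discriminant analysis on two PCA scores
#'
#' Reduces the spectra to two principal-component scores ([fit_pca()]), finds
#' the Fisher direction `w = Sw^-1 (mu_benign - mu_malignant)` in score space
#' (within-class scatter `Sw`, ridge-regularised by `ridge` when singular),
#' and fits one normal distribution per class on the projections. Prediction
#' evaluates the two class densities at the projected input and passes them
#' through a softmax.
#'
#' @param train A [spectra] object with at least 2 samples per class.
#' @param ridge Ridge added to the within-class scatter (default 1e-9).
#' @return An object of class `ftir_lda`.
#' @export
fit_lda <- function(train, ridge = 1e-9) {
  stopifnot(inherits(train, "spectra"))
  counts <- tabulate(train$labels, 2)
  if (any(counts < 2)) stop("need at least 2 samples per class", call. = FALSE)
  pca <- fit_pca(train)
  scores <- project(pca, train)
  is_mal <- train$labels == "malignant"
  mu_m <- colMeans(scores[is_mal, , drop = FALSE])
  mu_b <- colMeans(scores[!is_mal, , drop = FALSE])
  scatter <- function(s, mu) crossprod(sweep(s, 2, mu))
  sw <- scatter(scores[is_mal, , drop = FALSE], mu_m) +
    scatter(scores[!is_mal, , drop = FALSE], mu_b)
  w <- tryCatch(
    solve(sw, mu_b - mu_m),
    error = function(e) {
      warning("within-class scatter is singular; ridge-regularising", call. = FALSE)
      solve(sw + diag(ridge, 2), mu_b - mu_m)
    }
  )
  nw <- sqrt(sum(w^2))
  if (nw == 0) w <- c(1, 0) else w <- w / nw
  gamma <- drop(scores %*% w)
  class_stats <- function(g) {
    s <- stats::sd(g)
    if (!is.finite(s) || s == 0) s <- ridge + stats::sd(gamma) * 1e-6 + 1e-12
    c(mu = mean(g), sigma = s)
  }
  structure(
    list(pca = pca, fisher_direction = w,
         malignant = class_stats(gamma[is_mal]),
         benign = class_stats(gamma[!is_mal]),
         wavenumber = train$wavenumber),
    class = "ftir_lda"
  )
}

#' @export
print.ftir_lda <- function(x, ...) {
  cat(sprintf("<ftir_lda> gamma: malignant %.3g+/-%.3g, benign %.3g+/-%.3g\n",
              x$malignant["mu"], x$malignant["sigma"],
              x$benign["mu"], x$benign["sigma"]))
  invisible(x)
}

#' @rdname fit_lda
#' @param object A fitted `ftir_lda`.
#' @param newdata A [spectra] object on the training grid, or a score
#'   matrix/vector already in the 2-D PCA space.
#' @param ... Unused.
#' @return For `predict`: tibble with `p_benign`, `p_malignant` (softmax of
#'   the class normal densities at the projection) and `class`.
#' @export
predict.ftir_lda <- function(object, newdata, ...) {
  scores <- if (inherits(newdata, "spectra")) {
    project(object$pca, newdata)
  } else if (is.vector(newdata)) matrix(newdata, ncol = 2) else as.matrix(newdata)
  gamma <- drop(scores %*% object$fisher_direction)
  dm <- stats::dnorm(gamma, object$malignant["mu"], object$malignant["sigma"])
  db <- stats::dnorm(gamma, object$benign["mu"], object$benign["sigma"])
  p <- t(vapply(seq_along(gamma),
                function(i) softmax2(c(dm[i], db[i])), numeric(2)))
  # softmax([p_M, p_B]) -> reorder to (benign, malignant)
  prob_tibble(cbind(p[, 2], p[, 1]),
              if (inherits(newdata, "spectra")) newdata$ids else NULL)
}

#' Tidy the class statistics of a fitted LDA
#' @param x An `ftir_lda`.
#' @param ... Unused.
#' @return Tibble with one row per class: projected mean and SD.
#' @export
tidy.ftir_lda <- function(x, ...) {
  tibble::tibble(
    class = c("benign", "malignant"),
    mean = c(x$benign["mu"], x$malignant["mu"]),
    sd = c(x$benign["sigma"], x$malignant["sigma"])
  )
}
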