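#' Two-component principal component analysis of a spectral dataset
#'
#' Fits the top two principal components of the centered absorbance matrix.
#' The components are the leading eigenvectors of the (unnormalised) scatter
#' matrix `t(X - Xbar) %*% (X - Xbar)`; explained fractions are the leading
#' eigenvalues divided by the trace, so they are unaffected by the missing
#' 1/(N-1) factor. Computed via singular value decomposition for numerical
#' stability. Sign convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param x A [spectra] object with at least 3 samples.
#' @return An object of class `ftir_pca`: list with `mean` (length-L mean
#'   spectrum), `components` (L x 2 orthonormal loadings), `explained_fraction`
#'   (length 2), and `wavenumber`.
#' @export
fit_pca <- function(x) {
  stopifnot(inherits(x, "spectra"))
  X <- x$absorbance
  if (nrow(X) < 3) stop("PCA needs at least 3 samples", call. = FALSE)
  if (ncol(X) < 2) stop("PCA needs at least 2 channels", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(2, ncol(X)))
  eig <- sv$d^2
  total <- sum(eig)
  if (total <= 0) stop("data has rank 0; PCA undefined", call. = FALSE)
  comp <- sv$v[, 1:2, drop = FALSE]
  for (k in 1:2) {
    j <- which.max(abs(comp[, k]))
    if (comp[j, k] < 0) comp[, k] <- -comp[, k]
  }
  structure(
    list(mean = mu, components = comp,
         explained_fraction = eig[1:2] / total,
         wavenumber = x$wavenumber),
    class = "ftir_pca"
  )
}

#' @export
print.ftir_pca <- function(x, ...) {
  cat(sprintf("<ftir_pca> F1 = %.2f%%, F2 = %.2f%% of variance (%d channels)\n",
              100 * x$explained_fraction[1], 100 * x$explained_fraction[2],
              length(x$mean)))
  invisible(x)
}

#' Project spectra onto fitted principal components
#'
#' Computes the N x 2 score matrix `(X - Xbar) %*% [s_F1, s_F2]` using the
#' mean and loadings of the fitted model.
#'
#' @param model An [fit_pca()] model.
#' @param x A [spectra] object on the same grid.
#' @return Numeric N x 2 matrix of scores (columns `F1`, `F2`), with sample
#'   ids as rownames.
#' @export
project <- function(model, x) {
  stopifnot(inherits(model, "ftir_pca"), inherits(x, "spectra"))
  check_grid(model$wavenumber, x$wavenumber)
  scores <- sweep(x$absorbance, 2, model$mean) %*% model$components
  dimnames(scores) <- list(x$ids, c("F1", "F2"))
  scores
}

check_grid <- function(ref, grid) {
  if (length(ref) != length(grid) || max(abs(ref - grid)) > 1e-9) {
    stop("wavenumber grid does not match the one the model was fitted on",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Biplot tables: sample scores and per-wavenumber loadings
#'
#' @param model An [fit_pca()] model.
#' @param x A [spectra] object on the model grid.
#' @return A list of class `pca_biplot` with tibbles `scores` (`sample_id`,
#'   `label`, `F1`, `F2`; one row per sample) and `loadings`
#'   (`wavenumber_cm1`, `F1`, `F2`; one row per channel).
#' @export
biplot_table <- function(model, x) {
  scores <- project(model, x)
  structure(
    list(
      scores = tibble::tibble(
        sample_id = x$ids, label = as.character(x$labels),
        F1 = scores[, 1], F2 = scores[, 2]
      ),
      loadings = tibble::tibble(
        wavenumber_cm1 = model$wavenumber,
        F1 = model$components[, 1], F2 = model$components[, 2]
      ),
      explained_fraction = model$explained_fraction
    ),
    class = "pca_biplot"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the loadings of a fitted PCA
#' @param x An `ftir_pca` model.
#' @param ... Unused.
#' @return Tibble with `wavenumber_cm1`, `F1`, `F2` loadings.
#' @export
tidy.ftir_pca <- function(x, ...) {
  tibble::tibble(wavenumber_cm1 = x$wavenumber,
                 F1 = x$components[, 1], F2 = x$components[, 2])
}

#' One-row summary of a fitted PCA
#' @param x An `ftir_pca` model.
#' @param ... Unused.
#' @return Tibble with the two explained-variance fractions.
#' @export
glance.ftir_pca <- function(x, ...) {
  tibble::tibble(f1_fraction = x$explained_fraction[1],
                 f2_fraction = x$explained_fraction[2],
                 n_channels = length(x$mean))
}

#' PCA biplot
#'
#' Scatter of the sample scores coloured by diagnosis, with the strongest
#' loading vectors overlaid as arrows (scaled to the score range).
#'
#' @param object A `pca_biplot` from [biplot_table()].
#' @param n_loadings Number of largest-magnitude loading vectors to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.pca_biplot <- function(object, n_loadings = 10, ...) {
  sc <- object$scores
  ld <- object$loadings
  scale <- 0.8 * max(abs(c(sc$F1, sc$F2))) /
    max(sqrt(ld$F1^2 + ld$F2^2), .Machine$double.eps)
  ld <- dplyr::slice_max(ld, sqrt(.data$F1^2 + .data$F2^2), n = n_loadings)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$F1, y = .data$F2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.8) +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$F1 * scale, yend = .data$F2 * scale),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")), colour = "grey40"
    ) +
    ggplot2::labs(
      x = sprintf("F1 (%.1f%%)", 100 * object$explained_fraction[1]),
      y = sprintf("F2 (%.1f%%)", 100 * object$explained_fraction[2]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
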