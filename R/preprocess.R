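#' Per-spectrum z-score normalisation
#'
#' Centers a spectrum to mean 0 and scales it to unit sample standard
#' deviation (N-1 denominator). Affine-invariant: `znormalize(a*x + b)` equals
#' `znormalize(x)` for `a > 0`.
#'
#' @param values Numeric vector of absorbances (length >= 2).
#' @return Numeric vector with mean 0 and sample SD 1.
#' @examples
#' znormalize(c(1, 2, 3)) # -1, 0, 1
#' @export
znormalize <- function(values) {
  if (length(values) < 2) stop("need at least 2 channels to normalize", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-normalize a constant spectrum (zero standard deviation)", call. = FALSE)
  }
  (values - mean(values)) / s
}

#' Rubber-band baseline correction
#'
#' Estimates the baseline of a single spectrum as the lower convex hull of
#' the (wavenumber, absorbance) points, built from `n_points` evenly spaced
#' anchor candidates (both endpoints always included), linearly interpolated
#' over the full grid, and subtracts it. A straight-line spectrum is its own
#' hull, so affine trends are removed exactly; the corrected endpoints are 0.
#'
#' @param values Numeric absorbance vector.
#' @param wavenumber Matching wavenumber vector (any monotone order).
#' @param n_points Number of anchor candidates for the hull (default 64).
#' @return Corrected absorbance vector (input minus baseline).
#' @export
rubberband_baseline <- function(values, wavenumber, n_points = 64) {
  L <- length(values)
  stopifnot(length(wavenumber) == L)
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  if (n_points > L) stop("n_points exceeds the number of channels", call. = FALSE)
  ord <- order(wavenumber) # hull computed on ascending x
  x <- wavenumber[ord]
  y <- values[ord]
  anchors <- unique(round(seq(1, L, length.out = n_points)))
  hull <- lower_hull(x[anchors], y[anchors])
  baseline_sorted <- stats::approx(x[anchors][hull], y[anchors][hull],
                                   xout = x, rule = 2)$y
  baseline <- numeric(L)
  baseline[ord] <- baseline_sorted
  values - baseline
}

# Andrew's monotone chain, lower hull only; x strictly increasing.
# Returns indices of hull vertices in input order.
lower_hull <- function(x, y) {
  n <- length(x)
  keep <- integer(0)
  for (i in seq_len(n)) {
    while (length(keep) >= 2) {
      o <- keep[length(keep) - 1]
      a <- keep[length(keep)]
      cross <- (x[a] - x[o]) * (y[i] - y[o]) - (y[a] - y[o]) * (x[i] - x[o])
      if (cross <= 0) keep <- keep[-length(keep)] else break
    }
    keep <- c(keep, i)
  }
  keep
}

#' Crop a dataset to a wavenumber window
#'
#' Retains the channels with `low <= wavenumber <= high` (closed interval),
#' preserving the high-to-low grid order. The default window is the mid-IR
#' fingerprint region.
#'
#' @param x A [spectra] object.
#' @param high,low Window bounds in cm^-1.
#' @return A [spectra] object on the cropped grid.
#' @export
crop_fingerprint <- function(x, high = 1800, low = 850) {
  stopifnot(inherits(x, "spectra"))
  if (high < low) stop("window_high must exceed window_low", call. = FALSE)
  keep <- x$wavenumber >= low & x$wavenumber <= high
  if (!any(keep)) stop("crop window does not overlap the grid", call. = FALSE)
  out <- x
  out$wavenumber <- x$wavenumber[keep]
  out$absorbance <- x$absorbance[, keep, drop = FALSE]
  out
}

#' Preprocessing configuration
#'
#' Bundles the three per-spectrum preprocessing steps: z-score normalisation,
#' rubber-band baseline correction, and fingerprint cropping. The default
#' order (normalize, then baseline-correct, then crop) follows the order the
#' steps are conventionally reported for ATR-FTIR tissue spectra; it is fully
#' configurable.
#'
#' @param znorm,baseline,crop Logical; enable each step.
#' @param baseline_points Number of rubber-band anchor candidates (default 64).
#' @param window_high,window_low Fingerprint window in cm^-1 (defaults 1800 and
#'   850).
#' @param order Character vector giving the execution order of the enabled
#'   steps.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(znorm = TRUE, baseline = TRUE, crop = TRUE,
                              baseline_points = 64,
                              window_high = 1800, window_low = 850,
                              order = c("znorm", "baseline", "crop")) {
  if (baseline_points < 2) stop("baseline_points must be >= 2", call. = FALSE)
  if (window_high <= window_low) stop("window_high must exceed window_low", call. = FALSE)
  order <- match.arg(order, c("znorm", "baseline", "crop"), several.ok = TRUE)
  if (anyDuplicated(order)) stop("order must not repeat steps", call. = FALSE)
  enabled <- c(znorm = znorm, baseline = baseline, crop = crop)
  structure(
    list(znorm = znorm, baseline = baseline, crop = crop,
         baseline_points = baseline_points,
         window_high = window_high, window_low = window_low,
         order = order[enabled[order]]),
    class = "preprocess_config"
  )
}

#' Apply the preprocessing pipeline to a dataset
#'
#' Runs the enabled steps of `config` in `config$order`, per sample for the
#' normalisation and baseline steps. Deterministic; errors raised by a step
#' are annotated with the offending sample id.
#'
#' @param x A [spectra] object.
#' @param config A [preprocess_config()].
#' @return The preprocessed [spectra] object.
#' @export
preprocess <- function(x, config = preprocess_config()) {
  stopifnot(inherits(x, "spectra"), inherits(config, "preprocess_config"))
  per_sample <- function(x, fn) {
    for (i in seq_len(nrow(x$absorbance))) {
      x$absorbance[i, ] <- tryCatch(
        fn(x$absorbance[i, ]),
        error = function(e) stop("sample '", x$ids[i], "': ", conditionMessage(e),
                                 call. = FALSE)
      )
    }
    x
  }
  for (step in config$order) {
    x <- switch(step,
      znorm = per_sample(x, znormalize),
      baseline = per_sample(
        x, function(v) rubberband_baseline(v, x$wavenumber, config$baseline_points)
      ),
      crop = crop_fingerprint(x, config$window_high, config$window_low)
    )
  }
  x
}
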