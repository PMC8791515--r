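#' Default class-conditional absorbance bands
#'
#' Ten Gaussian bands at the fingerprint peak positions characteristic of
#' FFPE breast tissue spectra, with class-conditional amplitude means and
#' SDs (normalized-absorbance scale). Exactly five bands — 1452, 1399, 1337,
#' 1279 and 1236 cm^-1, the lipid / nucleic-acid / phospholipid region — are
#' class-discriminative; the remaining five (amide proteins, carbohydrates,
#' glycogen, phosphorylated proteins) share no mean shift large enough to
#' separate the classes.
#'
#' @param separation Optional target standardised gap for the discriminative
#'   bands: when given, the amplitude SDs of the five discriminative bands
#'   are rescaled so that `|mean_malignant - mean_benign| / SD` equals
#'   `separation` (both classes get the common rescaled SD). The means and
#'   all non-discriminative bands are untouched.
#' @param width_sigma Gaussian band width (SD) in cm^-1; 8 cm^-1 is a
#'   typical mid-IR bandwidth.
#' @return A tibble with one row per band: `center_malignant`,
#'   `center_benign`, `width_sigma`, `amp_mean_malignant`,
#'   `amp_sd_malignant`, `amp_mean_benign`, `amp_sd_benign`,
#'   `discriminative`.
#' @export
default_bands <- function(separation = NULL, width_sigma = 8) {
  bands <- tibble::tibble(
    center_malignant = c(1632, 1539, 1452, 1399, 1337, 1279, 1236, 1160, 1032, 880),
    center_benign    = c(1634, 1540, 1452, 1401, 1337, 1279, 1236, 1160, 1030, 878),
    width_sigma      = width_sigma,
    amp_mean_malignant = c(2.8311, 2.1152, 0.4797, 0.2208, -0.2794,
                           -0.4509, -0.0416, -0.8352, -0.1732, 0.1482),
    amp_sd_malignant   = c(0.2347, 0.2475, 0.2924, 0.2822, 0.3509,
                           0.3683, 0.4474, 0.2566, 0.3355, 1.0361),
    amp_mean_benign    = c(2.7934, 2.1533, 0.5920, 0.3375, -0.1598,
                           -0.3397, 0.1160, -0.7759, -0.2386, -0.0945),
    amp_sd_benign      = c(0.1968, 0.1955, 0.2651, 0.2481, 0.3269,
                           0.3479, 0.4204, 0.2634, 0.2966, 0.9590),
    discriminative = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                       FALSE, FALSE, FALSE)
  )
  if (!is.null(separation)) {
    stopifnot(separation > 0)
    d <- bands$discriminative
    gap <- abs(bands$amp_mean_malignant[d] - bands$amp_mean_benign[d])
    bands$amp_sd_malignant[d] <- gap / separation
    bands$amp_sd_benign[d] <- gap / separation
  }
  bands
}

#' Simulate a labelled FTIR-like fingerprint dataset
#'
#' Each spectrum is a sum of Gaussian bands with per-sample amplitudes drawn
#' from the class-conditional normal of each band, plus (optionally) a
#' per-sample random quadratic baseline drift, a random multiplicative gain
#' and additive offset (so that the preprocessing steps are exercised
#' non-trivially), and white noise. Fully reproducible given `seed`.
#'
#' The band amplitude tables are on the normalized (post z-score) scale and
#' so contain negative values; raw absorbance bands, however, are always
#' positive peaks — a "negative" normalized amplitude just means a peak
#' weaker than the spectrum mean. The generator therefore adds `band_floor`
#' to every drawn amplitude, producing physically sensible positive peaks
#' whose heights *relative to each other* follow the table; after baseline
#' correction and z-normalisation the peak values land back near the
#' tabulated scale (up to the per-spectrum affine normalisation).
#'
#' @param n_malignant,n_benign Sample counts (defaults 88 and 78, the scale
#'   of a realistic single-site FFPE study).
#' @param bands Band table as from [default_bands()].
#' @param wavenumber Grid (default 1800 to 850 cm^-1 at 2 cm^-1 steps, 476
#'   channels).
#' @param noise_sd Additive white-noise SD in absorbance units.
#' @param baseline_sd SD of the three random quadratic baseline
#'   coefficients; 0 disables drift.
#' @param gain_sd,offset_sd SD of the per-sample log-gain and offset; 0
#'   disables them.
#' @param band_floor Pedestal added to every drawn band amplitude so raw
#'   peaks are positive (default 3.5, clearing the most negative tabulated
#'   draw by about 3 SD).
#' @param seed Integer seed.
#' @return A [spectra] object; the generating band table is attached as
#'   `attr(, "bands")`.
#' @export
simulate_dataset <- function(n_malignant = 88, n_benign = 78,
                             bands = default_bands(),
                             wavenumber = seq(1800, 850, by = -2),
                             noise_sd = 0.02, baseline_sd = 0.05,
                             gain_sd = 0.05, offset_sd = 0.10,
                             band_floor = 3.5, seed = 1) {
  stopifnot(n_malignant >= 0, n_benign >= 0, n_malignant + n_benign >= 1,
            noise_sd >= 0, baseline_sd >= 0, gain_sd >= 0, offset_sd >= 0)
  L <- length(wavenumber)
  n <- n_malignant + n_benign
  labels <- rep(c("malignant", "benign"), c(n_malignant, n_benign))
  u <- (wavenumber - mean(wavenumber)) / diff(range(wavenumber)) # in [-0.5, 0.5]
  X <- withr::with_seed(seed, {
    X <- matrix(0, n, L)
    for (i in seq_len(n)) {
      mal <- labels[i] == "malignant"
      centers <- if (mal) bands$center_malignant else bands$center_benign
      mu <- if (mal) bands$amp_mean_malignant else bands$amp_mean_benign
      sdv <- if (mal) bands$amp_sd_malignant else bands$amp_sd_benign
      amps <- stats::rnorm(nrow(bands), mu, sdv) + band_floor
      s <- numeric(L)
      for (b in seq_len(nrow(bands))) {
        s <- s + amps[b] * exp(-(wavenumber - centers[b])^2 / (2 * bands$width_sigma[b]^2))
      }
      coef <- stats::rnorm(3, 0, baseline_sd)
      drift <- coef[1] + coef[2] * u + coef[3] * u^2
      gain <- exp(stats::rnorm(1, 0, gain_sd))
      offset <- stats::rnorm(1, 0, offset_sd)
      X[i, ] <- gain * (s + drift) + offset + stats::rnorm(L, 0, noise_sd)
    }
    X
  })
  out <- spectra(X, wavenumber, labels)
  attr(out, "bands") <- bands
  out
}

#' Channel mask of the discriminative bands
#'
#' TRUE for channels within `halfwidth_mult * width_sigma` of any
#' discriminative band center (union of the per-class centers).
#'
#' @param bands Band table as from [default_bands()].
#' @param wavenumber Grid vector.
#' @param halfwidth_mult Window half-width in units of the band SD.
#' @return Logical vector along the grid.
#' @export
ground_truth_mask <- function(bands, wavenumber, halfwidth_mult = 1) {
  mask <- rep(FALSE, length(wavenumber))
  d <- bands[bands$discriminative, , drop = FALSE]
  for (b in seq_len(nrow(d))) {
    hw <- halfwidth_mult * d$width_sigma[b]
    mask <- mask |
      abs(wavenumber - d$center_malignant[b]) <= hw |
      abs(wavenumber - d$center_benign[b]) <= hw
  }
  mask
}
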