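# Shared fixtures, all generated in code.

# tiny labelled dataset with an obvious class difference on two bands
toy_spectra <- function(n_per_class = 10, L = 24, gap = 2, noise = 0.2, seed = 1) {
  withr::with_seed(seed, {
    grid <- seq(1800, by = -2, length.out = L)
    base <- sin(seq(0, 3, length.out = L))
    X <- matrix(rnorm(2 * n_per_class * L, sd = noise), 2 * n_per_class, L,
                byrow = TRUE)
    X <- sweep(X, 2, base, `+`)
    j1 <- 2L
    j2 <- L - 1L
    X[seq_len(n_per_class), j1] <- X[seq_len(n_per_class), j1] + gap
    X[n_per_class + seq_len(n_per_class), j2] <-
      X[n_per_class + seq_len(n_per_class), j2] + gap
    spectra(X, grid, rep(c("malignant", "benign"), each = n_per_class))
  })
}

# the 1-D hard-margin toy: benign at -2, -1; malignant at +1, +2
svm_toy <- function() {
  spectra(matrix(c(-2, -1, 1, 2), ncol = 1), 1000,
          c("benign", "benign", "malignant", "malignant"))
}

# clean linearly separable generator configuration: the five discriminative
# fingerprint bands only, well separated
separable_bands <- function(separation = 2) {
  b <- default_bands(separation = separation)
  b[b$discriminative, ]
}

# band table whose single discriminative band dominates the mean spectrum
dominant_band_config <- function() {
  tibble::tibble(
    center_malignant = c(1452, 1100), center_benign = c(1452, 1100),
    width_sigma = 8,
    amp_mean_malignant = c(3.0, 1.0), amp_sd_malignant = c(0.15, 0.1),
    amp_mean_benign = c(2.0, 1.0), amp_sd_benign = c(0.15, 0.1),
    discriminative = c(TRUE, FALSE)
  )
}

expect_prob_pairs <- function(p, tol = 1e-9) {
  expect_true(all(abs(p$p_benign + p$p_malignant - 1) < tol))
}
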