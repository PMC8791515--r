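#' Perturbation fractions for the sensitivity sweep
#'
#' The symmetric grid of relative perturbations, -50% to +50% of a channel's
#' mean in 5% steps (21 values including 0).
#'
#' @return Numeric vector of length 21, strictly increasing, containing 0.
#' @export
perturbation_fractions <- function() seq(-10, 10) * 0.05

#' Ideal one-hot network outputs for labels
#'
#' Benign maps to (1, 0) and malignant to (0, 1), matching the
#' (p_benign, p_malignant) output order of the networks.
#'
#' @param labels Class label vector.
#' @return Numeric matrix, one row per label, two columns.
#' @export
ideal_output <- function(labels) {
  labels <- normalize_labels(labels)
  cbind(benign = as.numeric(labels == "benign"),
        malignant = as.numeric(labels == "malignant"))
}

#' Draw the experiment set for the sensitivity analysis
#'
#' Selects `round(fraction * N)` samples at random. With
#' `balanced = TRUE` (the default) the two classes contribute equally
#' (within one sample, the larger class taking the odd one); otherwise the
#' global class ratio is preserved.
#'
#' @param x A [spectra] object.
#' @param fraction Fraction of samples to draw (default 0.70).
#' @param balanced Equal class counts?
#' @param seed Integer seed.
#' @return A [spectra] object with the drawn samples.
#' @export
make_experiment_set <- function(x, fraction = 0.70, balanced = TRUE, seed = 1) {
  stopifnot(inherits(x, "spectra"), fraction > 0, fraction <= 1)
  n_exp <- round(fraction * n_samples(x))
  counts <- tabulate(x$labels, 2)
  names(counts) <- levels(x$labels)
  if (balanced) {
    half <- n_exp %/% 2
    take <- c(benign = half, malignant = half)
    if (n_exp %% 2 == 1) {
      larger <- names(counts)[which.max(counts)]
      take[larger] <- take[larger] + 1
    }
  } else {
    take <- largest_remainder(n_exp, counts / sum(counts))
    names(take) <- names(counts)
  }
  if (any(take > counts)) {
    stop("class counts too small for the requested draw (need ",
         paste(take, collapse = "/"), ", have ",
         paste(counts, collapse = "/"), ")", call. = FALSE)
  }
  idx <- withr::with_seed(seed, {
    unlist(lapply(names(take), function(cl) {
      pool <- which(as.character(x$labels) == cl)
      sample(pool, take[[cl]])
    }))
  })
  subset_samples(x, sort(idx))
}

#' Mean squared output response to one channel perturbation
#'
#' Adds `fraction * mean(channel j over the experiment set)` to channel `j`
#' of every sample, evaluates the network in inference mode, and returns the
#' squared deviation of the outputs from the ideal one-hot targets, halved
#' and averaged over samples, so the response lies in `[0, 1]`. With
#' `literal = TRUE` the printed difference-of-squares form
#' `sum (O^2 - Ohat^2) / 2` (summed, not averaged) is returned instead.
#'
#' @param model A trained [fnn].
#' @param s_exp The experiment [spectra] set.
#' @param j Channel index (1-based).
#' @param fraction Relative perturbation, typically in `[-0.5, 0.5]`.
#' @param literal Use the literal difference-of-squares form?
#' @return Scalar response.
#' @export
perturbed_mse <- function(model, s_exp, j, fraction, literal = FALSE) {
  stopifnot(inherits(model, "fnn"), inherits(s_exp, "spectra"))
  L <- n_channels(s_exp)
  if (j < 1 || j > L) stop("channel index out of range", call. = FALSE)
  X <- s_exp$absorbance
  X[, j] <- X[, j] + fraction * mean(X[, j])
  P <- forward(model, X, training = FALSE)
  ideal <- ideal_output(s_exp$labels)
  if (literal) {
    sum(P^2 - ideal^2) / 2
  } else {
    sum((P - ideal)^2) / (2 * nrow(X))
  }
}

#' Per-channel response of one network
#'
#' Arithmetic mean of [perturbed_mse()] over the perturbation grid.
#'
#' @inheritParams perturbed_mse
#' @param fractions Perturbation grid (default [perturbation_fractions()]).
#' @return Scalar mean response for channel `j`.
#' @export
input_response <- function(model, s_exp, j, fractions = perturbation_fractions(),
                           literal = FALSE) {
  mean(vapply(fractions, function(f) perturbed_mse(model, s_exp, j, f, literal),
              numeric(1)))
}

#' Committee perturbation sensitivity profile
#'
#' Trains `committee_size` networks of identical architecture, each with its
#' own seed and its own experiment-set draw, sweeps every channel of each
#' member's experiment set over the perturbation grid (networks evaluated in
#' inference mode, no retraining), and averages the per-channel responses
#' over the committee.
#'
#' @param x A preprocessed [spectra] object.
#' @param fnn_config An [fnn_config()] shared by all members (each member's
#'   seed is derived from `seed`).
#' @param committee_size Number of networks (reference design: 50).
#' @param exp_fraction Experiment-set fraction (default 0.70).
#' @param balanced Equal class counts in the experiment set?
#' @param fractions Perturbation grid.
#' @param literal Use the literal difference-of-squares response?
#' @param seed Integer master seed.
#' @return An object of class `sensitivity_profile`: `wavenumber`,
#'   `response` (committee mean per channel), `members`
#'   (committee_size x L matrix) and the configuration.
#' @export
committee_profile <- function(x, fnn_config = spectrasense::fnn_config(),
                              committee_size = 50, exp_fraction = 0.70,
                              balanced = TRUE,
                              fractions = perturbation_fractions(),
                              literal = FALSE, seed = 1) {
  stopifnot(inherits(x, "spectra"), committee_size >= 1)
  members <- matrix(NA_real_, committee_size, n_channels(x))
  for (m in seq_len(committee_size)) {
    member_seed <- seed + 104729L * m # distinct, stays well under 2^31
    res <- tryCatch({
      s_exp <- make_experiment_set(x, exp_fraction, balanced, seed = member_seed)
      cfg <- fnn_config
      cfg$seed <- member_seed
      fit <- train_fnn(s_exp, val = NULL, config = cfg)
      sweep_mat <- cpp_sensitivity_sweep(
        fit$weights, fit$biases, s_exp$absorbance, ideal_output(s_exp$labels),
        fractions, cfg$selu_lambda, cfg$selu_alpha, literal
      )
      rowMeans(sweep_mat)
    }, error = function(e) {
      stop("committee member with seed ", member_seed, " failed: ",
           conditionMessage(e), call. = FALSE)
    })
    members[m, ] <- res
  }
  structure(
    list(wavenumber = x$wavenumber, response = colMeans(members),
         members = members, committee_size = committee_size,
         fnn_config = fnn_config, exp_fraction = exp_fraction,
         balanced = balanced, fractions = fractions, literal = literal,
         seed = seed),
    class = "sensitivity_profile"
  )
}

#' @export
print.sensitivity_profile <- function(x, ...) {
  cat(sprintf("<sensitivity_profile> committee of %d over %d channels; response %.4g to %.4g\n",
              x$committee_size, length(x$response),
              min(x$response), max(x$response)))
  invisible(x)
}

#' Tidy a sensitivity profile
#' @param x A `sensitivity_profile`.
#' @param ... Unused.
#' @return Tibble with `wavenumber_cm1`, `mse_mean`, `mse_sd`, `n_members`.
#' @export
tidy.sensitivity_profile <- function(x, ...) {
  tibble::tibble(
    wavenumber_cm1 = x$wavenumber,
    mse_mean = x$response,
    mse_sd = apply(x$members, 2, stats::sd),
    n_members = x$committee_size
  )
}

#' Extract contiguous high-response wavenumber regions
#'
#' Channels whose committee response exceeds the rule threshold
#' (`mean_plus_sd`: mean + 1 SD of the profile; `top_fraction`: the upper
#' `top_fraction` quantile) are merged into maximal contiguous runs.
#'
#' @param profile A `sensitivity_profile`.
#' @param rule Threshold rule.
#' @param top_fraction Fraction for the `top_fraction` rule (default 0.10).
#' @return Tibble with one row per region: `high_cm1`, `low_cm1`,
#'   `peak_cm1`, `peak_response`, `n_channels`. Empty for a flat profile.
#' @export
significant_regions <- function(profile, rule = c("mean_plus_sd", "top_fraction"),
                                top_fraction = 0.10) {
  stopifnot(inherits(profile, "sensitivity_profile"))
  rule <- match.arg(rule)
  r <- profile$response
  thr <- switch(rule,
    mean_plus_sd = mean(r) + stats::sd(r),
    top_fraction = stats::quantile(r, 1 - top_fraction, names = FALSE)
  )
  over <- which(r > thr)
  if (length(over) == 0) {
    return(tibble::tibble(high_cm1 = numeric(), low_cm1 = numeric(),
                          peak_cm1 = numeric(), peak_response = numeric(),
                          n_channels = integer()))
  }
  runs <- split(over, cumsum(c(1, diff(over) != 1)))
  purrr::map_dfr(runs, function(idx) {
    peak <- idx[which.max(r[idx])]
    tibble::tibble(
      high_cm1 = max(profile$wavenumber[idx]),
      low_cm1 = min(profile$wavenumber[idx]),
      peak_cm1 = profile$wavenumber[peak],
      peak_response = r[peak],
      n_channels = length(idx)
    )
  })
}

#' Sensitivity profile line plot
#' @param object A `sensitivity_profile`.
#' @param ... Unused.
#' @return A ggplot of the committee-mean response per wavenumber (x axis
#'   reversed, high wavenumbers left, as spectra are conventionally drawn).
#' @export
autoplot.sensitivity_profile <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wavenumber_cm1, y = .data$mse_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mse_mean - .data$mse_sd,
                                      ymax = .data$mse_mean + .data$mse_sd),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "wavenumber (cm^-1)", y = "mean squared response") +
    ggplot2::theme_minimal()
}
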