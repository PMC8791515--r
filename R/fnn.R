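#' Feed-forward network configuration
#'
#' Architecture and training hyperparameters for the from-scratch SELU
#' networks: `n_hidden_layers` fully connected hidden layers of constant
#' `width`, a 2-node softmax output, binary cross-entropy loss, per-sample
#' AdaGrad stochastic gradient descent, alpha-dropout with keep probability
#' `dropout_keep`, Gaussian weight initialisation with per-layer SD equal to
#' 1/fan-in, and zero biases. Defaults mirror the reference architecture
#' (2 hidden layers of 350 neurons, learning rate 0.01, 1000 epochs);
#' examples and tests use smaller values.
#'
#' @param n_hidden_layers Number of hidden layers (2, 4 or 8 in the reference
#'   designs; any positive integer is accepted).
#' @param width Neurons per hidden layer.
#' @param learning_rate Positive AdaGrad learning rate.
#' @param epochs Training epochs (full passes over the training set).
#' @param dropout_keep Alpha-dropout keep probability in (0, 1].
#' @param selu_lambda,selu_alpha SELU constants (canonical self-normalising
#'   values).
#' @param seed Integer seed governing initialisation, shuffling and dropout.
#' @param batch_size Only per-sample SGD (`1`) is implemented.
#' @return A `fnn_config` list.
#' @export
fnn_config <- function(n_hidden_layers = 2, width = 350, learning_rate = 0.01,
                       epochs = 1000, dropout_keep = 0.9,
                       selu_lambda = 1.0507009873554805,
                       selu_alpha = 1.6732632423543772,
                       seed = 1, batch_size = 1) {
  stopifnot(n_hidden_layers >= 1, width >= 1, learning_rate > 0,
            epochs >= 0, dropout_keep > 0, dropout_keep <= 1,
            batch_size == 1)
  structure(
    list(n_hidden_layers = as.integer(n_hidden_layers),
         width = as.integer(width), learning_rate = learning_rate,
         epochs = as.integer(epochs), dropout_keep = dropout_keep,
         selu_lambda = selu_lambda, selu_alpha = selu_alpha,
         seed = as.integer(seed), batch_size = 1L),
    class = "fnn_config"
  )
}

#' Scaled exponential linear unit
#'
#' `lambda * v` for `v > 0` and `lambda * alpha * (exp(v) - 1)` for
#' `v <= 0`; continuous at 0 and saturating at `-lambda * alpha`.
#'
#' @param v Numeric vector (or scalar).
#' @param lambda,alpha SELU constants.
#' @return Same shape as `v`.
#' @export
selu <- function(v, lambda = 1.0507009873554805, alpha = 1.6732632423543772) {
  ifelse(v > 0, lambda * v, lambda * alpha * (exp(v) - 1))
}

#' Two-class softmax
#'
#' @param logits Numeric 2-vector.
#' @return Positive 2-vector summing to 1; shift-invariant.
#' @export
softmax2 <- function(logits) {
  stopifnot(length(logits) == 2, all(is.finite(logits)))
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Binary cross-entropy against a one-hot target
#'
#' Computed on the malignant output of the two-way softmax:
#' `-(y log p + (1 - y) log(1 - p))` with `p` the predicted malignant
#' probability, clamped to `[1e-12, 1 - 1e-12]`.
#'
#' @param predicted Probability 2-vector `(p_benign, p_malignant)`.
#' @param ideal One-hot 2-vector: benign `(1, 0)`, malignant `(0, 1)`.
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(predicted, ideal) {
  stopifnot(length(predicted) == 2, length(ideal) == 2)
  eps <- 1e-12
  p <- min(max(predicted[2], eps), 1 - eps)
  y <- ideal[2]
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Initialise a feed-forward network
#'
#' Weights are drawn from Normal(0, sd = 1/fan-in of the layer); biases start
#' at zero, as do the AdaGrad accumulators. Deterministic given
#' `config$seed`.
#'
#' @param config An [fnn_config()].
#' @param input_size Number of input channels L.
#' @return An object of class `fnn`.
#' @export
init_fnn <- function(config, input_size) {
  stopifnot(inherits(config, "fnn_config"), input_size >= 1)
  par <- withr::with_seed(config$seed,
    cpp_init_fnn(as.integer(input_size), config$width, config$n_hidden_layers))
  new_fnn(par$weights, par$biases, config, input_size)
}

new_fnn <- function(weights, biases, config, input_size,
                    gw = NULL, gb = NULL, trained_epochs = 0L,
                    history = NULL, wavenumber = NULL) {
  if (is.null(gw)) gw <- lapply(weights, function(w) array(0, dim(w)))
  if (is.null(gb)) gb <- lapply(biases, function(b) numeric(length(b)))
  if (is.null(history)) {
    history <- tibble::tibble(epoch = integer(), loss = numeric(),
                              val_accuracy = numeric())
  }
  structure(
    list(weights = weights, biases = biases, adagrad_w = gw, adagrad_b = gb,
         config = config, input_size = as.integer(input_size),
         trained_epochs = as.integer(trained_epochs),
         history = history, wavenumber = wavenumber),
    class = "fnn"
  )
}

#' @export
print.fnn <- function(x, ...) {
  cat(sprintf("<fnn> %d -> %s -> 2 (SELU/softmax), %d epoch(s) trained\n",
              x$input_size,
              paste(rep(x$config$width, x$config$n_hidden_layers), collapse = "-"),
              x$trained_epochs))
  invisible(x)
}

#' Forward pass through a network
#'
#' Inference mode (`training = FALSE`, the default) applies no dropout and is
#' deterministic. With `training = TRUE`, alpha-dropout with the configured
#' keep probability is applied after every hidden SELU layer, consuming R's
#' RNG stream.
#'
#' @param model An `fnn`.
#' @param x Numeric vector (one spectrum), matrix (samples x channels), or a
#'   [spectra] object on the training grid.
#' @param training Apply dropout?
#' @return Matrix of probabilities with columns `p_benign`, `p_malignant`.
#' @export
forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "fnn"))
  X <- as_input_matrix(model, x)
  p <- cpp_forward(model$weights, model$biases, X,
                   model$config$selu_lambda, model$config$selu_alpha,
                   training, model$config$dropout_keep)
  colnames(p) <- c("p_benign", "p_malignant")
  p
}

as_input_matrix <- function(model, x) {
  if (inherits(x, "spectra")) {
    if (!is.null(model$wavenumber)) check_grid(model$wavenumber, x$wavenumber)
    x <- x$absorbance
  }
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$input_size) {
    stop("input has ", ncol(x), " channels; model expects ", model$input_size,
         call. = FALSE)
  }
  x
}

#' Analytic gradients of the loss for one sample
#'
#' Backpropagated gradients of the binary cross-entropy at a single input
#' (no dropout), for inspection and finite-difference verification.
#'
#' @param model An `fnn`.
#' @param x Numeric input vector of length `input_size`.
#' @param label `"benign"` or `"malignant"`.
#' @return List with per-layer weight gradients `gw`, bias gradients `gb`,
#'   and the `loss` value.
#' @export
fnn_gradients <- function(model, x, label) {
  stopifnot(inherits(model, "fnn"), length(x) == model$input_size)
  y <- as.integer(normalize_labels(label) == "malignant")
  cpp_grad_single(model$weights, model$biases, x, y,
                  model$config$selu_lambda, model$config$selu_alpha)
}

#' One AdaGrad update
#'
#' Accumulates squared gradients (`G <- G + g^2`) and applies
#' `theta <- theta - lr * g / (sqrt(G) + 1e-8)` to every parameter of the
#' model.
#'
#' @param model An `fnn`.
#' @param gradients A list as returned by [fnn_gradients()] (elements `gw`,
#'   `gb` matching the model layers).
#' @param learning_rate Positive step size.
#' @return The updated `fnn`.
#' @export
adagrad_step <- function(model, gradients, learning_rate) {
  stopifnot(inherits(model, "fnn"), learning_rate > 0)
  eps <- 1e-8
  for (l in seq_along(model$weights)) {
    gw <- gradients$gw[[l]]
    gb <- as.numeric(gradients$gb[[l]])
    if (!all(is.finite(gw)) || !all(is.finite(gb))) {
      stop("non-finite gradient", call. = FALSE)
    }
    model$adagrad_w[[l]] <- model$adagrad_w[[l]] + gw^2
    model$weights[[l]] <- model$weights[[l]] -
      learning_rate * gw / (sqrt(model$adagrad_w[[l]]) + eps)
    model$adagrad_b[[l]] <- model$adagrad_b[[l]] + gb^2
    model$biases[[l]] <- as.numeric(model$biases[[l]]) -
      learning_rate * gb / (sqrt(model$adagrad_b[[l]]) + eps)
  }
  model
}

#' Train a feed-forward network
#'
#' Per-sample AdaGrad SGD with seeded shuffling for `config$epochs` epochs,
#' binary cross-entropy loss on the softmax outputs, and alpha-dropout after
#' every hidden layer. Fully deterministic given `config$seed`. With
#' `epochs = 0` the initialised model is returned unchanged.
#'
#' @param train A [spectra] object containing both classes.
#' @param val Optional [spectra] validation set; per-epoch validation
#'   accuracy is recorded in the history when supplied.
#' @param config An [fnn_config()].
#' @return A trained `fnn`; `$history` is a tibble with per-epoch `loss` and
#'   `val_accuracy`.
#' @export
train_fnn <- function(train, val = NULL, config = fnn_config()) {
  stopifnot(inherits(train, "spectra"), inherits(config, "fnn_config"))
  if (length(unique(train$labels)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  X <- train$absorbance
  y <- as.integer(train$labels == "malignant")
  has_val <- !is.null(val)
  if (has_val) {
    check_grid(train$wavenumber, val$wavenumber)
    Xval <- val$absorbance
    yval <- as.integer(val$labels == "malignant")
  } else {
    Xval <- matrix(0, 1, ncol(X))
    yval <- 0L
  }
  fit <- withr::with_seed(config$seed, {
    par <- cpp_init_fnn(ncol(X), config$width, config$n_hidden_layers)
    gw0 <- lapply(par$weights, function(w) array(0, dim(w)))
    gb0 <- lapply(par$biases, function(b) numeric(length(b)))
    if (config$epochs == 0) {
      list(weights = par$weights, biases = par$biases, gw = gw0, gb = gb0,
           loss = numeric(), val_accuracy = numeric())
    } else {
      cpp_train_fnn(par$weights, par$biases, gw0, gb0, X, y, Xval, yval,
                    has_val, config$epochs, config$learning_rate,
                    config$dropout_keep, config$selu_lambda,
                    config$selu_alpha)
    }
  })
  history <- tibble::tibble(
    epoch = seq_len(config$epochs),
    loss = as.numeric(fit$loss),
    val_accuracy = as.numeric(fit$val_accuracy)
  )
  new_fnn(fit$weights, fit$biases, config, ncol(X),
          gw = fit$gw, gb = fit$gb, trained_epochs = config$epochs,
          history = history, wavenumber = train$wavenumber)
}

#' Predict class probabilities from a trained network
#'
#' @param object A trained `fnn`.
#' @param newdata A [spectra] object (grid-checked) or numeric matrix.
#' @param ... Unused.
#' @return A tibble with `p_benign`, `p_malignant` and the thresholded
#'   `class` (malignant when `p_malignant > 0.5`).
#' @export
predict.fnn <- function(object, newdata, ...) {
  p <- forward(object, newdata, training = FALSE)
  prob_tibble(p, if (inherits(newdata, "spectra")) newdata$ids else NULL)
}

prob_tibble <- function(p, ids = NULL) {
  out <- tibble::tibble(
    p_benign = unname(p[, 1]), p_malignant = unname(p[, 2]),
    class = factor(ifelse(p[, 2] > 0.5, "malignant", "benign"),
                   levels = label_levels)
  )
  if (!is.null(ids)) out <- tibble::add_column(out, sample_id = ids, .before = 1)
  out
}

#' Training history of a fitted network
#' @param x A trained `fnn`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `val_accuracy`.
#' @export
tidy.fnn <- function(x, ...) x$history

#' One-row training summary of a fitted network
#' @param x A trained `fnn`.
#' @param ... Unused.
#' @return Tibble with architecture and final-loss columns.
#' @export
glance.fnn <- function(x, ...) {
  tibble::tibble(
    n_hidden_layers = x$config$n_hidden_layers, width = x$config$width,
    learning_rate = x$config$learning_rate, epochs = x$trained_epochs,
    final_loss = if (nrow(x$history) > 0) x$history$loss[nrow(x$history)] else NA_real_,
    final_val_accuracy = if (nrow(x$history) > 0) x$history$val_accuracy[nrow(x$history)] else NA_real_
  )
}

# ---- hyperparameter grids ---------------------------------------------------

#' Learning-rate search grid
#'
#' Ten rates generated by the recurrence `l0 = 1`, `l_i = l_{i-1} / k` with
#' `k = 2` for odd `i` and `k = 5` for even `i`: 1, 0.5, 0.1, ..., 5e-5.
#'
#' @return Numeric vector of length 10, descending.
#' @export
learning_rate_grid <- function() {
  rates <- numeric(10)
  rates[1] <- 1
  for (i in 2:10) {
    k <- if ((i - 1) %% 2 == 1) 2 else 5
    rates[i] <- rates[i - 1] / k
  }
  rates
}

#' Layer-width search grid
#'
#' The fixed 20-element set of hidden-layer widths explored during
#' optimisation.
#'
#' @return Integer vector of length 20, ascending.
#' @export
layer_width_grid <- function() {
  c(10L, 15L, 20L, 25L, 30L, 40L, 50L, 60L, 80L, 100L, 120L, 140L, 160L,
    180L, 200L, 250L, 300L, 350L, 400L, 462L)
}

#' Grid search over learning rate and layer width
#'
#' For every (learning rate, width) pair and each requested depth, networks
#' are trained on the training portion of stratified Monte-Carlo splits and
#' the final validation accuracy is averaged over all (trial, fold) splits.
#' The pair with the highest mean validation accuracy wins (ties go to the
#' earlier grid entry).
#'
#' @param x A [spectra] object.
#' @param depths Hidden-layer counts to search (default 2).
#' @param rates,widths Grids to explore; default the full
#'   [learning_rate_grid()] and [layer_width_grid()].
#' @param trials,folds Monte-Carlo cross-validation plan passed to
#'   [make_splits()].
#' @param epochs,dropout_keep Training settings for every candidate.
#' @param seed Integer seed for the split plan and all trainings.
#' @return An `fnn_grid_search` list: `best` (one row per depth) and
#'   `surface` (one row per depth x rate x width) tibbles.
#' @export
grid_search_fnn <- function(x, depths = 2, rates = learning_rate_grid(),
                            widths = layer_width_grid(), trials = 1,
                            folds = 3, epochs = 100, dropout_keep = 0.9,
                            seed = 1) {
  stopifnot(inherits(x, "spectra"), trials >= 1)
  splits <- make_splits(x$labels, trials = trials, folds = folds, seed = seed)
  grid <- tidyr::expand_grid(depth = depths, learning_rate = rates, width = widths)
  res <- purrr::pmap_dfr(grid, function(depth, learning_rate, width) {
    acc <- purrr::map_dbl(seq_len(nrow(splits)), function(i) {
      cfg <- fnn_config(n_hidden_layers = depth, width = width,
                        learning_rate = learning_rate, epochs = epochs,
                        dropout_keep = dropout_keep,
                        seed = seed + i)
      fit <- train_fnn(subset_samples(x, splits$train[[i]]),
                       val = NULL, config = cfg)
      val <- subset_samples(x, splits$val[[i]])
      mean(predict(fit, val)$class == val$labels)
    })
    tibble::tibble(depth = depth, learning_rate = learning_rate,
                   width = width, mean_val_acc = mean(acc),
                   sd_val_acc = stats::sd(acc))
  })
  best <- res |>
    dplyr::group_by(.data$depth) |>
    dplyr::slice_max(.data$mean_val_acc, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  structure(list(best = best, surface = res), class = "fnn_grid_search")
}

#' Validation-accuracy surface of a grid search
#' @param object An `fnn_grid_search`.
#' @param ... Unused.
#' @return A ggplot tile plot of mean validation accuracy.
#' @export
autoplot.fnn_grid_search <- function(object, ...) {
  ggplot2::ggplot(object$surface,
                  ggplot2::aes(x = factor(.data$learning_rate),
                               y = factor(.data$width),
                               fill = .data$mean_val_acc)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~depth, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "learning rate", y = "hidden-layer width",
                  fill = "mean val. accuracy") +
    ggplot2::theme_minimal()
}
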