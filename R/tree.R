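#' Best binary split of one feature by Gini impurity
#'
#' Candidate thresholds are the midpoints between consecutive distinct sorted
#' values. The default score is the weighted Gini impurity of the two
#' children, `sum_child (N_child / N) * (1 - sum_m p_m^2)`, minimised with
#' ties broken toward the smallest threshold. `literal = TRUE` instead
#' minimises the purity-style quantity
#' `sum_m (N_m|split / N) * (P(m)^2 + (1 - P(m))^2)` as sometimes printed for
#' Gini's diversity index; it is kept only as a documented option because it
#' rewards impure splits.
#'
#' @param values Numeric feature values, one per sample.
#' @param labels Class labels (benign/malignant).
#' @param literal Use the literal printed form of the index?
#' @return A list with `threshold` and `score`, or `NULL` when no split
#'   exists (all values identical, or a single class).
#' @export
gini_best_split <- function(values, labels, literal = FALSE) {
  if (length(values) < 2) return(NULL)
  labels <- normalize_labels(labels)
  if (length(unique(labels)) < 2) return(NULL)
  s <- best_split_col(values, as.integer(labels == "malignant"), literal)
  if (is.null(s)) NULL else list(threshold = s[1], score = s[2])
}

# workhorse on a numeric column and 0/1 malignant indicator; returns
# c(threshold, score) or NULL
best_split_col <- function(v, mal, literal) {
  ord <- order(v)
  v <- v[ord]
  mal <- mal[ord]
  n <- length(v)
  boundary <- which(diff(v) > 0) # split after these sorted positions
  if (length(boundary) == 0) return(NULL)
  thresholds <- (v[boundary] + v[boundary + 1]) / 2
  cum_mal <- cumsum(mal)
  n_l <- boundary
  mal_l <- cum_mal[boundary]
  ben_l <- n_l - mal_l
  n_r <- n - n_l
  mal_r <- cum_mal[n] - mal_l
  ben_r <- n_r - mal_r
  if (literal) {
    # printed form: sum_m (N_m|split / N_t) * (P(m|t)^2 + (1 - P(m|t))^2)
    p_mal <- cum_mal[n] / n
    score <- (mal_l / n) * (p_mal^2 + (1 - p_mal)^2) +
      (ben_l / n) * ((1 - p_mal)^2 + p_mal^2)
  } else {
    gini_l <- 1 - (mal_l / n_l)^2 - (ben_l / n_l)^2
    gini_r <- 1 - (mal_r / n_r)^2 - (ben_r / n_r)^2
    score <- (n_l / n) * gini_l + (n_r / n) * gini_r
  }
  best <- which.min(score) # first minimum = smallest threshold
  c(thresholds[best], score[best])
}

# best (feature, threshold) over all columns of X for 0/1 indicator mal
best_split_matrix <- function(X, mal, literal = FALSE) {
  if (length(mal) < 2 || length(unique(mal)) < 2) return(NULL)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    s <- best_split_col(X[, j], mal, literal)
    if (!is.null(s) && (is.null(best) || s[2] < best$score)) {
      best <- list(feature = j, threshold = s[1], score = s[2])
    }
  }
  best
}

# Flat tree representation: parallel vectors over node ids. feature NA marks
# a leaf; children are node ids.
new_flat_tree <- function() {
  list(feature = integer(), threshold = numeric(), left = integer(),
       right = integer(), p_mal = numeric(), n = integer())
}

add_node <- function(tree, p_mal, n) {
  id <- length(tree$feature) + 1L
  tree$feature[id] <- NA_integer_
  tree$threshold[id] <- NA_real_
  tree$left[id] <- NA_integer_
  tree$right[id] <- NA_integer_
  tree$p_mal[id] <- p_mal
  tree$n[id] <- n
  list(tree = tree, id = id)
}

flat_tree_prob <- function(tree, X) {
  out <- numeric(nrow(X))
  recurse <- function(id, rows) {
    if (length(rows) == 0) return()
    if (is.na(tree$feature[id])) {
      out[rows] <<- tree$p_mal[id]
      return()
    }
    left <- X[rows, tree$feature[id]] <= tree$threshold[id]
    recurse(tree$left[id], rows[left])
    recurse(tree$right[id], rows[!left])
  }
  recurse(1L, seq_len(nrow(X)))
  out
}

flat_tree_depth <- function(tree) {
  depth_of <- function(id) {
    if (is.na(tree$feature[id])) return(0L)
    1L + max(depth_of(tree$left[id]), depth_of(tree$right[id]))
  }
  if (length(tree$feature) == 0) 0L else depth_of(1L)
}

#' Grow a CART decision tree with validation-accuracy stopping
#'
#' Recursive binary splitting on the (feature, threshold) pair with minimal
#' weighted Gini impurity. The frontier is deepened one level at a time;
#' after each level expansion the validation accuracy is evaluated and
#' growth stops as soon as it decreases, reverting to the previous tree.
#' Leaves store the class proportions of the training samples they contain.
#' Deterministic.
#'
#' @param train A [spectra] object.
#' @param val A [spectra] object used for the stopping rule.
#' @param max_depth Hard depth cap (default unlimited).
#' @param literal Use the literal printed Gini form (see
#'   [gini_best_split()]).
#' @return An object of class `ftir_tree`.
#' @export
grow_tree <- function(train, val, max_depth = Inf, literal = FALSE) {
  stopifnot(inherits(train, "spectra"), inherits(val, "spectra"))
  if (n_samples(train) == 0 || n_samples(val) == 0) {
    stop("train and validation sets must be non-empty", call. = FALSE)
  }
  check_grid(train$wavenumber, val$wavenumber)
  X <- train$absorbance
  mal <- as.integer(train$labels == "malignant")
  Xv <- val$absorbance
  yv <- val$labels == "malignant"
  val_acc <- function(tree) mean((flat_tree_prob(tree, Xv) > 0.5) == yv)

  made <- add_node(new_flat_tree(), mean(mal), length(mal))
  tree <- made$tree
  frontier <- list(list(id = made$id, rows = seq_along(mal)))
  acc <- val_acc(tree)
  depth <- 0
  while (length(frontier) > 0 && depth < max_depth) {
    proposals <- list()
    for (f in frontier) {
      s <- best_split_matrix(X[f$rows, , drop = FALSE], mal[f$rows], literal)
      if (!is.null(s)) proposals[[length(proposals) + 1]] <- c(f, s)
    }
    if (length(proposals) == 0) break
    cand <- tree
    new_frontier <- list()
    for (p in proposals) {
      left_rows <- p$rows[X[p$rows, p$feature] <= p$threshold]
      right_rows <- setdiff(p$rows, left_rows)
      made <- add_node(cand, mean(mal[left_rows]), length(left_rows))
      cand <- made$tree; lid <- made$id
      made <- add_node(cand, mean(mal[right_rows]), length(right_rows))
      cand <- made$tree; rid <- made$id
      cand$feature[p$id] <- p$feature
      cand$threshold[p$id] <- p$threshold
      cand$left[p$id] <- lid
      cand$right[p$id] <- rid
      new_frontier <- c(new_frontier,
                        list(list(id = lid, rows = left_rows),
                             list(id = rid, rows = right_rows)))
    }
    a <- val_acc(cand)
    if (a < acc) break
    tree <- cand
    acc <- a
    frontier <- new_frontier
    depth <- depth + 1
  }
  structure(
    list(nodes = tree, depth = flat_tree_depth(tree), val_accuracy = acc,
         wavenumber = train$wavenumber),
    class = "ftir_tree"
  )
}

#' @export
print.ftir_tree <- function(x, ...) {
  cat(sprintf("<ftir_tree> depth %d (%d nodes), validation accuracy %.3f\n",
              x$depth, length(x$nodes$feature), x$val_accuracy))
  invisible(x)
}

#' @rdname grow_tree
#' @param object A fitted `ftir_tree`.
#' @param newdata A [spectra] object or matrix on the training grid.
#' @param ... Unused.
#' @return For `predict`: tibble with `p_benign`, `p_malignant` (leaf class
#'   proportions) and `class`.
#' @export
predict.ftir_tree <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectra")) {
    check_grid(object$wavenumber, newdata$wavenumber)
    newdata$absorbance
  } else if (is.vector(newdata)) matrix(newdata, nrow = 1) else as.matrix(newdata)
  p_mal <- flat_tree_prob(object$nodes, X)
  prob_tibble(cbind(1 - p_mal, p_mal),
              if (inherits(newdata, "spectra")) newdata$ids else NULL)
}

#' Random forest of CART trees on bootstrap resamples
#'
#' Each tree is grown by [grow_tree()] on a row bootstrap of the training
#' set (no feature subsampling), using the shared validation set for its
#' stopping rule. The forest diagnosis is the prevailing vote of the trees,
#' with ties resolved toward malignant; the reported malignancy probability
#' is the fraction of trees voting malignant.
#'
#' @param train,val [spectra] objects.
#' @param n_trees Number of bagged trees.
#' @param seed Integer seed for the bootstrap draws.
#' @param max_depth Per-tree depth cap.
#' @return An object of class `ftir_rf`.
#' @export
fit_rf <- function(train, val, n_trees = 10, seed = 1, max_depth = Inf) {
  stopifnot(n_trees >= 1)
  n <- n_samples(train)
  trees <- withr::with_seed(seed, {
    lapply(seq_len(n_trees), function(k) {
      idx <- sample.int(n, n, replace = TRUE)
      grow_tree(subset_samples(train, idx), val, max_depth = max_depth)
    })
  })
  structure(
    list(trees = trees, n_trees = n_trees, seed = seed,
         wavenumber = train$wavenumber),
    class = "ftir_rf"
  )
}

#' @export
print.ftir_rf <- function(x, ...) {
  cat(sprintf("<ftir_rf> %d trees, depths %s\n", x$n_trees,
              paste(vapply(x$trees, function(t) t$depth, numeric(1)),
                    collapse = ",")))
  invisible(x)
}

#' @rdname fit_rf
#' @param object A fitted `ftir_rf`.
#' @param newdata A [spectra] object or matrix on the training grid.
#' @param ... Unused.
#' @return For `predict`: tibble with the malignant vote fraction as
#'   `p_malignant` and the majority-vote `class` (ties go to malignant).
#' @export
predict.ftir_rf <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectra")) {
    check_grid(object$wavenumber, newdata$wavenumber)
    newdata$absorbance
  } else if (is.vector(newdata)) matrix(newdata, nrow = 1) else as.matrix(newdata)
  votes <- vapply(object$trees,
                  function(t) as.numeric(flat_tree_prob(t$nodes, X) > 0.5),
                  numeric(nrow(X)))
  if (nrow(X) == 1) votes <- matrix(votes, nrow = 1)
  frac <- rowMeans(votes)
  out <- prob_tibble(cbind(1 - frac, frac),
                     if (inherits(newdata, "spectra")) newdata$ids else NULL)
  out$class <- factor(ifelse(frac >= 0.5, "malignant", "benign"),
                      levels = label_levels)
  out
}

#' Grid search over the forest size
#'
#' Fits forests of every size in `sizes`, `trials` times each with distinct
#' seeds, and returns the size with the highest mean validation accuracy
#' (ties to the smallest size).
#'
#' @param train,val [spectra] objects.
#' @param sizes Integer vector of tree counts to try (default 3:100).
#' @param trials Repetitions per size.
#' @param seed Base seed.
#' @param max_depth Per-tree depth cap.
#' @return A list with `best_n_trees` and a `surface` tibble
#'   (`n_trees`, `mean_val_acc`, `sd_val_acc`).
#' @export
rf_size_search <- function(train, val, sizes = 3:100, trials = 5, seed = 1,
                           max_depth = Inf) {
  surface <- purrr::map_dfr(sizes, function(nt) {
    acc <- vapply(seq_len(trials), function(tr) {
      fit <- fit_rf(train, val, n_trees = nt, seed = seed + 1000 * tr + nt,
                    max_depth = max_depth)
      mean(predict(fit, val)$class == val$labels)
    }, numeric(1))
    tibble::tibble(n_trees = nt, mean_val_acc = mean(acc),
                   sd_val_acc = stats::sd(acc))
  })
  list(best_n_trees = surface$n_trees[which.max(surface$mean_val_acc)],
       surface = surface)
}
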