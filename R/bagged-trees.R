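# Ensemble of bagged trees (EBT): CART base learners with Gini impurity,
# grown best-first under a split-count cap, bagged over full-size bootstrap
# samples (no feature subsampling -- this is bagging, not a random forest).
# Predictions average the per-tree leaf class distributions.

as_design_matrix <- function(X) {
  if (inherits(X, "feature_matrix") || is.data.frame(X)) {
    X <- feature_values(X)
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X
}

as_class_factor <- function(y) {
  if (!is.factor(y)) y <- factor(y)
  # sleep-stage labels always use the canonical six-class order
  if (all(levels(y) %in% stage_levels())) {
    y <- factor(as.character(y), levels = stage_levels())
  }
  y
}

#' Fit a single CART decision tree
#'
#' CART growth with Gini impurity: at each step the open node with the
#' largest total impurity decrease receives the best split (threshold at the
#' midpoint of consecutive distinct sorted values); growth stops at purity or
#' when \code{max_splits} internal nodes exist.  Ties resolve to the lowest
#' feature index, then the lowest threshold, so growth is deterministic.
#'
#' @param X numeric matrix or \code{"feature_matrix"} (rows = samples).
#' @param y class labels (factor or character).
#' @param max_splits cap on the number of internal nodes; \code{0} yields a
#'   majority-class stump.
#' @return object of class \code{"cart_tree"}.
#' @export
fit_tree <- function(X, y, max_splits = nrow(as_design_matrix(X)) - 1L) {
  X <- as_design_matrix(X)
  y <- as_class_factor(y)
  if (nrow(X) < 1L) stop("cannot fit a tree on an empty sample", call. = FALSE)
  if (nrow(X) != length(y)) stop("X and y sizes differ", call. = FALSE)
  tree <- .cart_grow(X, as.integer(y) - 1L, nlevels(y), as.integer(max_splits))
  structure(list(tree = tree, classes = levels(y),
                 max_splits = as.integer(max_splits)),
            class = "cart_tree")
}

#' @export
predict.cart_tree <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  P <- .cart_predict(object$tree, as_design_matrix(newdata))
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' Fit an ensemble of bagged trees
#'
#' Each tree is trained on a bootstrap sample of size \code{n} drawn
#' uniformly with replacement; out-of-bag (OOB) predictions aggregate the
#' trees whose bootstrap missed each sample.  Deterministic given
#' \code{seed}.
#'
#' @inheritParams fit_tree
#' @param n_learners number of bagged trees.
#' @param max_splits split cap per tree (default \code{n - 1}: full growth).
#' @param seed integer seed for the bootstrap draws.
#' @param learning_rate accepted for interface parity with boosting-style
#'   tooling and ignored by bagging (a note is emitted when supplied).
#' @return object of class \code{"bagged_trees"} with the trees, class order,
#'   bootstrap indices and OOB error.
#' @export
fit_bagged <- function(X, y, n_learners = 30L, max_splits = NULL, seed = 1L,
                       learning_rate = NULL) {
  X <- as_design_matrix(X)
  y <- as_class_factor(y)
  n <- nrow(X)
  if (n < 1L) stop("cannot fit on an empty sample", call. = FALSE)
  if (!is.null(learning_rate)) {
    message("fit_bagged: 'learning_rate' has no effect on bagging; ignored")
  }
  if (is.null(max_splits)) max_splits <- n - 1L
  n_learners <- as.integer(n_learners)
  stopifnot(n_learners >= 1L)
  boot <- with_seed(seed, {
    lapply(seq_len(n_learners), function(t) sample.int(n, n, replace = TRUE))
  })
  trees <- lapply(boot, function(idx) {
    .cart_grow(X[idx, , drop = FALSE], as.integer(y)[idx] - 1L,
               nlevels(y), as.integer(max_splits))
  })
  # OOB: average leaf distributions over trees that did not see the sample
  acc <- matrix(0, n, nlevels(y))
  cnt <- numeric(n)
  for (t in seq_len(n_learners)) {
    out <- setdiff(seq_len(n), unique(boot[[t]]))
    if (!length(out)) next
    acc[out, ] <- acc[out, ] + .cart_predict(trees[[t]], X[out, , drop = FALSE])
    cnt[out] <- cnt[out] + 1
  }
  covered <- cnt > 0
  oob_error <- if (any(covered)) {
    pred <- max.col(acc[covered, , drop = FALSE], ties.method = "first")
    mean(pred != as.integer(y)[covered])
  } else NA_real_
  structure(list(trees = trees, classes = levels(y),
                 n_learners = n_learners, max_splits = as.integer(max_splits),
                 seed = as.integer(seed), oob_error = oob_error),
            class = "bagged_trees")
}

#' @export
predict.bagged_trees <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as_design_matrix(newdata)
  P <- matrix(0, nrow(X), length(object$classes))
  for (tr in object$trees) P <- P + .cart_predict(tr, X)
  P <- P / length(object$trees)
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.bagged_trees <- function(x, ...) {
  cat(sprintf("Ensemble of bagged trees: %d learners, max_splits = %d, OOB error = %s\n",
              x$n_learners, x$max_splits,
              ifelse(is.na(x$oob_error), "NA", sprintf("%.4f", x$oob_error))))
  invisible(x)
}

#' Hyperparameter sweep for the bagged ensemble
#'
#' k-fold cross-validated misclassification rate over a grid of ensemble
#' sizes and split caps; the optimum is the grid point with the smallest
#' error, ties resolving to fewer trees, then fewer splits.  The per-point
#' error curve (misclassification rate versus number of trees) is returned
#' for plotting.
#'
#' @inheritParams fit_bagged
#' @param tree_grid integer vector of ensemble sizes (e.g. \code{c(10, 250)}).
#' @param split_grid integer vector of split caps.
#' @param k folds.
#' @return list with \code{error_surface} (data.frame: n_learners,
#'   max_splits, cv_error) and \code{best} (named list).
#' @export
tune_bagged <- function(X, y, tree_grid, split_grid, k = 5L, seed = 1L) {
  stopifnot(length(tree_grid) >= 1L, length(split_grid) >= 1L)
  X <- as_design_matrix(X)
  y <- as_class_factor(y)
  folds <- stratified_folds(y, k, seed = derive_seed(seed, "tune"))
  grid <- expand.grid(n_learners = as.integer(tree_grid),
                      max_splits = as.integer(split_grid))
  grid$cv_error <- vapply(seq_len(nrow(grid)), function(gi) {
    errs <- vapply(seq_len(k), function(fi) {
      tr <- folds != fi
      fit <- fit_bagged(X[tr, , drop = FALSE], y[tr],
                        n_learners = grid$n_learners[gi],
                        max_splits = grid$max_splits[gi],
                        seed = derive_seed(seed, "tune", gi, fi))
      mean(predict(fit, X[!tr, , drop = FALSE]) != y[!tr])
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  ord <- order(grid$cv_error, grid$n_learners, grid$max_splits)
  best <- grid[ord[1L], ]
  list(error_surface = grid,
       best = list(n_learners = best$n_learners,
                   max_splits = best$max_splits,
                   cv_error = best$cv_error))
}
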