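test_that("a separable 1-D problem yields a single midpoint split", {
  X <- matrix(c(1, 2, 3, 4), ncol = 1)
  y <- c("A", "A", "B", "B")
  tree <- fit_tree(X, y, max_splits = 5)
  expect_identical(tree$tree$n_splits, 1L)
  expect_identical(tree$tree$feature[1], 0L)
  expect_identical(tree$tree$threshold[1], 2.5)
  expect_identical(as.character(predict(tree, X)), y)
})

test_that("pure nodes and a zero split cap yield stumps", {
  X <- matrix(rnorm(10), ncol = 1)
  expect_identical(fit_tree(X, rep("A", 10))$tree$n_splits, 0L)
  y <- c(rep("A", 7), rep("B", 3))
  stump <- fit_tree(X, y, max_splits = 0)
  expect_identical(stump$tree$n_splits, 0L)
  expect_true(all(predict(stump, X) == "A"))   # majority class
  expect_error(fit_tree(X[0, , drop = FALSE], character(0)), "empty")
})

test_that("full-depth trees interpolate distinct points; ensembles are seed-deterministic", {
  X <- matrix(with_seed_test(1, rnorm(60)), ncol = 2)
  y <- rep(c("A", "B", "C"), each = 10)
  one <- fit_bagged(X, y, n_learners = 1, seed = 5)
  m <- fit_bagged(X, y, n_learners = 7, seed = 5)
  probe <- matrix(with_seed_test(2, rnorm(40)), ncol = 2)
  expect_identical(predict(m, probe),
                   predict(fit_bagged(X, y, n_learners = 7, seed = 5), probe))
  p <- predict(m, probe, type = "prob")
  expect_equal(unname(rowSums(p)), rep(1, 20), tolerance = 1e-12)
  # permuting the trees leaves the averaged prediction unchanged
  m2 <- m
  m2$trees <- rev(m2$trees)
  expect_identical(predict(m2, probe), predict(m, probe))
  # single-tree ensemble reduces to that tree
  expect_identical(unname(predict(one, probe, type = "prob")),
                   unname(.cart_predict_wrap(one$trees[[1]], probe)))
})

test_that("bagging beats chance out of bag and never loses to its worst member in training", {
  fm <- test_features(30, seed = 42)
  m <- fit_bagged(fm, fm$label, n_learners = 20, seed = 2)
  expect_lt(m$oob_error, 5 / 6)
  Xm <- as.matrix(fm[, attr(fm, "feature_names")])
  ens_err <- mean(predict(m, Xm) != fm$label)
  single_errs <- vapply(m$trees, function(tr) {
    pr <- .cart_predict_wrap(tr, Xm)
    mean(m$classes[max.col(pr, ties.method = "first")] != as.character(fm$label))
  }, 1)
  expect_lte(ens_err, max(single_errs))
})

test_that("ensemble accuracy is comparable to an independent random-forest reference", {
  skip_if_not_installed("randomForest")
  fm <- test_features(30, seed = 42)
  Xm <- as.matrix(fm[, attr(fm, "feature_names")])
  ours <- fit_bagged(fm, fm$label, n_learners = 40, seed = 3)$oob_error
  rf <- randomForest::randomForest(Xm, fm$label, ntree = 40,
                                   mtry = ncol(Xm))   # mtry = p: bagging
  theirs <- mean(rf$predicted != fm$label)
  expect_lt(abs(ours - theirs), 0.15)
})

test_that("the tuning sweep returns valid errors and finds separable structure", {
  fm <- test_features(30, seed = 42)
  one <- tune_bagged(fm, fm$label, tree_grid = 5, split_grid = 20, k = 3, seed = 1)
  expect_identical(nrow(one$error_surface), 1L)
  expect_identical(one$best$n_learners, 5L)
  res <- tune_bagged(fm, fm$label, tree_grid = c(5, 25),
                     split_grid = c(10, 100), k = 3, seed = 1)
  expect_true(all(res$error_surface$cv_error >= 0 & res$error_surface$cv_error <= 1))
  expect_lt(res$best$cv_error, 0.05)
})

test_that("fitted ensembles serialize to JSON text and reload with identical predictions", {
  fm <- test_features(10, seed = 21)
  m <- fit_bagged(fm, fm$label, n_learners = 5, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_bagged_trees(m, path)
  m2 <- read_bagged_trees(path)
  Xm <- as.matrix(fm[, attr(fm, "feature_names")])
  expect_identical(predict(m2, Xm), predict(m, Xm))
  expect_equal(predict(m2, Xm, type = "prob"), predict(m, Xm, type = "prob"),
               tolerance = 1e-12)
})

test_that("the inert learning-rate parameter is accepted with a note", {
  X <- matrix(rnorm(20), ncol = 2)
  y <- rep(c("A", "B"), 5)
  expect_message(fit_bagged(X, y, n_learners = 2, seed = 1, learning_rate = 1),
                 "no effect")
})
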