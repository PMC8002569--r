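test_that("confusion matrices tabulate in canonical order with exact counts", {
  y <- factor(c("W", "S1", "S2", "W", "REM"), levels = stage_levels())
  p <- factor(c("W", "S2", "S2", "W", "REM"), levels = stage_levels())
  cm <- confusion_matrix(y, p)
  expect_identical(sum(cm), 5L)
  expect_identical(rownames(cm), stage_levels())
  expect_identical(cm["S1", "S2"], 1L)
  # perfect predictions: 100 on the row-percent diagonal
  cmp <- confusion_matrix(y, y)
  expect_true(all(diag(row_percent(cmp))[table(y) > 0] == 100))
  # constant predictor: first column holds 100% of every row
  allw <- confusion_matrix(y, factor(rep("W", 5), levels = stage_levels()))
  expect_true(all(row_percent(allw)[as.character(unique(y)), "W"] == 100))
  expect_true(all(abs(rowSums(row_percent(cm))[table(y) > 0] - 100) < 1e-9))
})

test_that("overall accuracy: identity, chance and diagonal-weighted identities", {
  eye <- cm_from_row_percent(diag(6) * 100, rep(10, 6))
  expect_identical(overall_accuracy(eye), 100)
  unif <- cm_from_row_percent(matrix(100 / 6, 6, 6), rep(600, 6))
  expect_equal(overall_accuracy(unif), 100 / 6, tolerance = 1e-9)
  # accuracy equals the row-count-weighted mean of diagonal row-percentages
  cm <- cm_from_row_percent(cap_confusion_table("healthy_unbalanced")$pct,
                            cap_confusion_table("healthy_unbalanced")$row_totals)
  w <- rowSums(cm) / sum(cm)
  expect_equal(overall_accuracy(cm), sum(w * diag(row_percent(cm))),
               tolerance = 1e-9)
})

test_that("published insomnia balanced table reconstructs its printed metrics", {
  tab <- cap_confusion_table("insomnia_balanced")
  cm <- cm_from_row_percent(tab$pct, tab$row_totals)
  expect_equal(overall_accuracy(cm), 92.8, tolerance = 2e-3)
  # uniform true marginals make the chance agreement exactly 1/6
  N <- sum(cm)
  pe <- sum(rowSums(cm) * colSums(cm)) / N^2
  expect_equal(pe, 1 / 6, tolerance = 1e-3)
  expect_equal(cohens_kappa(cm), 0.9145, tolerance = 0.002)
  expect_equal(round(f1_per_class(cm, "REM"), 2), 0.93)
})

test_that("published healthy table reconstructs the one-vs-rest stage accuracies", {
  tab <- cap_confusion_table("healthy_unbalanced")
  cm <- cm_from_row_percent(tab$pct, tab$row_totals)
  # printed per-class list: 95.84, 94.94, 85.87, 92.4, 96.59, 91.95 (rounding
  # of the percent table moves the reconstruction by ~0.05)
  printed <- c(W = 95.84, S1 = 94.94, S2 = 85.87, S3 = 92.4,
               S4 = 96.59, REM = 91.95)
  for (cl in names(printed)) {
    expect_equal(per_class_ovr_accuracy(cm, cl), printed[[cl]], tolerance = 0.002)
  }
})

test_that("kappa: perfect, independent and degenerate cases", {
  eye <- cm_from_row_percent(diag(6) * 100, rep(50, 6))
  expect_identical(cohens_kappa(eye), 1)
  # independence with matching marginals: outer-product counts give kappa 0
  r <- c(100, 50, 200, 80, 120, 150)
  indep <- round(outer(r, r) / sum(r))
  m <- structure(indep, dimnames = list(stage_levels(), stage_levels()),
                 class = c("confusion_matrix", "matrix"))
  expect_lt(abs(cohens_kappa(m)), 0.01)
  # kappa never exceeds the accuracy proportion when chance agreement > 0
  tab <- cap_confusion_table("healthy_unbalanced")
  cm <- cm_from_row_percent(tab$pct, tab$row_totals)
  expect_lte(cohens_kappa(cm), overall_accuracy(cm) / 100)
})

test_that("trial aggregation uses the population standard deviation", {
  acc <- cap_healthy_trial_accuracies()
  expect_equal(mean(acc), 78.3, tolerance = 0.01)
  expect_equal(pop_sd(acc), 1.21, tolerance = 0.005)
  # the sample (n-1) convention would NOT reproduce the published 1.21
  expect_gt(abs(sd(acc) - 1.21), 0.1)
})

test_that("majority-class baseline equals its closed-form rate on the healthy counts", {
  counts <- cap_epoch_counts()[, "healthy"]
  y <- factor(rep(names(counts), counts), levels = stage_levels())
  pred <- factor(rep("S2", length(y)), levels = stage_levels())
  expect_equal(overall_accuracy(confusion_matrix(y, pred)),
               100 * 2172 / 6063, tolerance = 1e-9)
})

test_that("stratified folds keep class proportions within one sample", {
  y <- factor(rep(stage_levels(), times = c(45, 28, 217, 57, 118, 141)),
              levels = stage_levels())
  folds <- getFromNamespace("stratified_folds", "sleepwave")(y, 10, seed = 3)
  for (cl in stage_levels()) {
    per_fold <- table(factor(folds[y == cl], levels = 1:10))
    expect_lte(diff(range(per_fold)), 1)
  }
})

test_that("repeated CV is deterministic, rejects tiny classes and reports sane metrics", {
  fm <- test_features(30, seed = 42)
  cv1 <- repeated_cv(fm, fm$label, n_learners = 10, k = 5, trials = 2, seed = 9)
  cv2 <- repeated_cv(fm, fm$label, n_learners = 10, k = 5, trials = 2, seed = 9)
  expect_identical(cv1$per_trial_accuracy, cv2$per_trial_accuracy)
  expect_identical(unclass(cv1$confusion), unclass(cv2$confusion))
  expect_true(all(cv1$per_trial_accuracy >= 0 & cv1$per_trial_accuracy <= 100))
  expect_true(cv1$kappa_mean >= -1 && cv1$kappa_mean <= 1)
  expect_identical(sum(cv1$confusion), length(fm$label) * 2L)
  expect_equal(cv1$mean_accuracy, mean(cv1$per_trial_accuracy))
  expect_equal(cv1$std_accuracy, pop_sd(cv1$per_trial_accuracy))
  tiny <- fm[c(1:3, 31:60, 61:90, 91:120, 121:150, 151:180), ]
  expect_error(repeated_cv(tiny, tiny$label, k = 5), "fewer than k")
})

test_that("one-vs-rest ROC: perfect separation, permutation chance and monotone invariance", {
  y <- factor(rep(c("W", "S2"), each = 50), levels = stage_levels())
  s_perfect <- cbind(W = c(rep(1, 50), rep(0, 50)),
                     S2 = c(rep(0, 50), rep(1, 50)))
  roc <- roc_ovr(s_perfect, y, classes = c("W", "S2"))
  expect_identical(roc$W$auc, 1)
  # scores independent of labels: AUC concentrates at 1/2 over permutations
  s <- with_seed_test(4, runif(100))
  aucs <- vapply(1:40, function(i) {
    yp <- with_seed_test(100 + i, sample(as.character(y)))
    roc_ovr(cbind(W = s), yp, classes = "W")$W$auc
  }, 1)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # monotone transform invariance
  a1 <- roc_ovr(cbind(W = s), y, classes = "W")$W$auc
  a2 <- roc_ovr(cbind(W = exp(3 * s)), y, classes = "W")$W$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  y <- with_seed_test(6, sample(c("W", "S2"), 80, replace = TRUE))
  s <- with_seed_test(7, runif(80) + 0.8 * (y == "W"))
  ours <- roc_ovr(cbind(W = s), y, classes = "W")$W$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(response = y == "W", predictor = s,
                                           quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})
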