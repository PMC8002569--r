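test_that("norms evaluate exactly on hand-checkable vectors", {
  expect_identical(lm_norm(c(3, -4), 1), 7)
  expect_identical(lm_norm(c(3, -4), 2), 5)
  expect_identical(lm_norm(numeric(5), 2), 0)
  expect_identical(linf_norm(c(3, -4)), 4)
  expect_identical(linf_norm(0), 0)
  expect_message(expect_identical(lm_norm(numeric(0), 1), 0), "empty")
})

test_that("norm inequalities linf <= l2 <= l1 hold on random vectors and real sub-bands", {
  for (r in 1:100) {
    u <- with_seed_test(r, rnorm(sample(2:50, 1)))
    expect_lte(linf_norm(u), lm_norm(u, 2) + 1e-12)
    expect_lte(lm_norm(u, 2), lm_norm(u, 1) + 1e-12)
  }
  fm <- test_features(10, seed = 21)
  fn <- attr(fm, "feature_names")
  for (sb in 1:6) {
    l1 <- fm[[sprintf("F4-C4_Sb%d_l1", sb)]]
    l2 <- fm[[sprintf("F4-C4_Sb%d_l2", sb)]]
    li <- fm[[sprintf("F4-C4_Sb%d_linf", sb)]]
    expect_true(all(li <= l2 + 1e-9) && all(l2 <= l1 + 1e-9))
  }
})

test_that("per-epoch features: 18 per channel, 36 combined, zero epoch gives zeros", {
  bank <- small_bank()
  rec <- list(samples = list("F4-C4" = with_seed_test(1, rnorm(3840)),
                             "C4-A1" = with_seed_test(2, rnorm(3840))),
              label = "W", subject_id = "s", group = "healthy", epoch_index = 0)
  f1 <- epoch_features(rec, bank, "F4-C4")
  expect_length(f1, 18L)
  expect_identical(names(f1)[1:3], c("F4-C4_Sb1_l1", "F4-C4_Sb1_l2", "F4-C4_Sb1_linf"))
  f2 <- epoch_features(rec, bank, c("F4-C4", "C4-A1"))
  expect_length(f2, 36L)
  expect_identical(f2[1:18], f1)
  zero <- rec
  zero$samples <- lapply(zero$samples, function(x) x * 0)
  expect_true(all(epoch_features(zero, bank, c("F4-C4", "C4-A1")) == 0))
  expect_error(epoch_features(rec, bank, "O1-A2"), "lacks channel")
})

test_that("features scale exactly linearly with the signal", {
  bank <- small_bank()
  rec <- list(samples = list("F4-C4" = with_seed_test(5, rnorm(3840))),
              label = "W", subject_id = "s", group = "healthy", epoch_index = 0)
  f <- epoch_features(rec, bank, "F4-C4")
  rec$samples[["F4-C4"]] <- 3.5 * rec$samples[["F4-C4"]]
  expect_equal(epoch_features(rec, bank, "F4-C4"), 3.5 * f, tolerance = 1e-12)
})

test_that("the feature matrix has one row per epoch, in input order", {
  set <- test_cohort(5, seed = 9)
  fm <- build_feature_matrix(set, small_bank())
  expect_identical(nrow(fm), 30L)
  expect_identical(attr(fm, "feature_names"), names(fm)[1:18])
  expect_identical(as.character(fm$label), vapply(set$records, `[[`, "", "label"))
  # permutation equivariance
  perm <- with_seed_test(2, sample(30))
  setp <- epoch_set(set$records[perm], set$channels, set$fs, set$epoch_s)
  fmp <- build_feature_matrix(setp, small_bank())
  expect_equal(as.matrix(fmp[, 1:18]), as.matrix(fm[perm, 1:18]),
               ignore_attr = TRUE)
  empty <- epoch_set(list(), set$channels, set$fs, set$epoch_s)
  expect_identical(nrow(build_feature_matrix(empty, small_bank())), 0L)
})

test_that("deep-sleep epochs maximize the coarse-band l1 norm", {
  fm <- test_features(50, seed = 42)
  m <- tapply(fm[["F4-C4_Sb1_l1"]], fm$label, mean)
  expect_identical(names(which.max(m)), "S4")
})

test_that("feature matrices roundtrip through CSV", {
  fm <- test_features(10, seed = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  got <- read_feature_matrix(path)
  expect_equal(as.matrix(got[, attr(fm, "feature_names")]),
               as.matrix(fm[, attr(fm, "feature_names")]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(as.character(got$label), as.character(fm$label))
})
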