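test_that("epoch generation is deterministic with the documented length and RMS", {
  x <- generate_epoch("W", fs = 512, epoch_s = 30, seed = 1)
  expect_length(x, 15360L)
  expect_identical(generate_epoch("W", fs = 512, epoch_s = 30, seed = 1), x)
  expect_false(identical(generate_epoch("W", fs = 512, epoch_s = 30, seed = 2), x))
  # scaled to the profile's RMS amplitude exactly
  prof <- stage_profiles()
  expect_equal(sqrt(mean(x^2)), prof$W$amplitude_scale, tolerance = 1e-9)
  expect_error(generate_epoch("N3", 512, 30, 1), "unknown stage")
  expect_error(generate_epoch("W", fs = 64), "fs must be")
})

test_that("deep sleep carries more delta power than REM (periodogram oracle)", {
  p_s4 <- p_rem <- numeric(20)
  for (s in 1:20) {
    p_s4[s] <- band_power(generate_epoch("S4", 512, 30, seed = s), 512, 0.5, 4)
    p_rem[s] <- band_power(generate_epoch("REM", 512, 30, seed = s), 512, 0.5, 4)
  }
  expect_gt(mean(p_s4), mean(p_rem))
})

test_that("mean delta power is strictly ordered S4 > S3 > S2 > REM", {
  mean_delta <- vapply(c("S4", "S3", "S2", "REM"), function(st) {
    mean(vapply(1:50, function(s) {
      band_power(generate_epoch(st, 128, 30, seed = 1000 + s), 128, 0.5, 4)
    }, 1))
  }, 1)
  expect_true(all(diff(mean_delta) < 0))
})

test_that("cohorts honour the requested counts, labels and seed contract", {
  counts <- c(W = 3, S1 = 1, S2 = 5, S3 = 2, S4 = 2, REM = 4)
  spec <- cohort_spec(list(healthy = counts, insomnia = counts[c(1, 3)]),
                      fs = 128, epoch_s = 2, seed = 5)
  set <- generate_cohort(spec)
  expect_identical(length(set), 17L + 8L)
  grp <- vapply(set$records, `[[`, "", "group")
  tab <- table(grp, as.character(epoch_labels(set)))
  expect_identical(as.integer(tab["healthy", names(counts)]),
                   as.integer(counts))
  expect_identical(as.integer(tab["insomnia", c("W", "S2")]),
                   as.integer(counts[c(1, 3)]))

  empty <- generate_cohort(cohort_spec(list(healthy = c(W = 0)), fs = 128,
                                       epoch_s = 2, seed = 1))
  expect_identical(length(empty), 0L)

  # same label multiset, different samples under a different master seed
  set2 <- generate_cohort(cohort_spec(list(healthy = counts, insomnia = counts[c(1, 3)]),
                                      fs = 128, epoch_s = 2, seed = 6))
  expect_identical(table(epoch_labels(set2)), table(epoch_labels(set)))
  expect_false(identical(set2$records[[1]]$samples, set$records[[1]]$samples))

  # per-epoch streams depend only on (seed, group, stage, index, channel):
  # permuting the group list does not change a given epoch
  setp <- generate_cohort(cohort_spec(list(insomnia = counts[c(1, 3)], healthy = counts),
                                      fs = 128, epoch_s = 2, seed = 5))
  pick <- function(s) Filter(function(r) r$group == "healthy" && r$label == "S2",
                             s$records)[[2]]
  expect_identical(pick(setp)$samples, pick(set)$samples)
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(list(healthy = c(W = -1)), seed = 1), ">= 0")
  expect_error(cohort_spec(list(healthy = c(XX = 5)), seed = 1), "unknown stages")
  expect_error(cohort_spec(list(healthy = c(W = 1)), fs = 0), "positive")
})
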