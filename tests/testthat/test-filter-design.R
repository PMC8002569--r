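test_that("maximal-regularity length-7 design equals the closed-form maxflat filter", {
  h <- design_halfband_analysis(7, R = 2, alpha = 1, gamma = 0)
  expect_equal(as.numeric(h), c(-1, 0, 9, 16, 9, 0, -1) / 32, tolerance = 1e-14)
  # four zeros at pi in the alternating-moment sense
  expect_identical(vanishing_moments(h), 4L)
  expect_equal(as.numeric(maxflat_halfband(7)), as.numeric(h))
})

test_that("halfband structure is exact by construction, never approximate", {
  for (L in c(7, 11, 15)) {
    for (R in 0:2) {
      h <- design_halfband_analysis(L, omega_p = 0.35 * pi, alpha = 0.9,
                                    gamma = 0.1, R = R)
      c0 <- (L - 1) / 2
      expect_identical(as.numeric(h)[c0 + 1], 0.5)
      expect_identical(verify_halfband(h), 0)
    }
  }
  # hand-built non-halfband filter is flagged with its worst deviation
  expect_equal(verify_halfband(c(1, 1, 1, 1, 1) / 5), 1 / 5)
})

test_that("halfband identity A(w) + A(pi - w) = 1 holds on a dense grid", {
  w <- seq(0, pi, length.out = 2001)
  for (L in c(7, 11, 15)) {
    h <- design_halfband_analysis(L, omega_p = 0.4 * pi, R = 1)
    dev <- amplitude_response(h, w) + amplitude_response(h, pi - w) - 1
    expect_lt(max(abs(dev)), 1e-12)
  }
})

test_that("optimized stopband energy is no worse than a brute-force grid search", {
  # L = 11, R = 1, pure band-error objective: two free dimensions after the
  # A(pi) = 0 constraint; exhaustive 0.01-resolution grid as optimality oracle
  wp <- 0.4 * pi
  h <- design_halfband_analysis(11, omega_p = wp, alpha = 1, gamma = 0, R = 1)
  wgrid <- seq(pi - wp, pi, length.out = 2001)
  es_direct <- function(a1, a2, a3) {
    A <- 0.5 + 2 * (a1 * cos(wgrid) + a2 * cos(3 * wgrid) + a3 * cos(5 * wgrid))
    sum((A[-1]^2 + A[-length(A)]^2) / 2) * (wgrid[2] - wgrid[1])
  }
  cand <- expand.grid(a2 = seq(-0.2, 0.2, by = 0.01),
                      a3 = seq(-0.2, 0.2, by = 0.01))
  cand$a1 <- 0.25 - cand$a2 - cand$a3
  grid_best <- min(mapply(es_direct, cand$a1, cand$a2, cand$a3))
  a <- attr(h, "free_taps")
  expect_lte(es_direct(a[1], a[2], a[3]), grid_best + 1e-10)
  # and strictly better than the maxflat filter of the same length
  am <- attr(maxflat_halfband(11), "free_taps")
  expect_lt(es_direct(a[1], a[2], a[3]), es_direct(am[1], am[2], am[3]))
})

test_that("stopband energy is monotone non-increasing in filter length", {
  es <- vapply(c(7, 11, 15), function(L) {
    h <- design_halfband_analysis(L, omega_p = 0.4 * pi, alpha = 1,
                                  gamma = 0, R = 1)
    w <- seq(pi - 0.4 * pi, pi, length.out = 4001)
    A <- amplitude_response(h, w)
    sum((A[-1]^2 + A[-length(A)]^2) / 2) * (w[2] - w[1])
  }, numeric(1))
  expect_true(all(diff(es) <= 1e-12))
})

test_that("synthesis lowpass satisfies PR, moments and symmetry exactly", {
  h0 <- maxflat_halfband(7)
  f0 <- design_synthesis_lowpass(h0, 9, V = 2)
  p <- convolve(as.numeric(h0), rev(as.numeric(f0)), type = "open")
  d <- (7 + 9 - 2) / 2
  even_off <- seq(2, d, by = 2)
  expect_lt(max(abs(p[d + 1 + even_off]), abs(p[d + 1 - even_off])), 1e-12)
  expect_equal(p[d + 1], 1, tolerance = 1e-12)
  n <- 0:8
  expect_lt(abs(sum((-1)^n * as.numeric(f0))), 1e-12)       # V >= 1 moment
  expect_equal(as.numeric(f0), rev(as.numeric(f0)))         # linear phase
  expect_gte(vanishing_moments(f0), 2)
})

test_that("infeasible length or constraint combinations are rejected with a rank report", {
  h0 <- design_halfband_analysis(15, R = 2)
  expect_error(design_synthesis_lowpass(h0, 9, V = 2), "infeasible")
  expect_error(design_halfband_analysis(7, R = 3), "free taps")
  expect_error(design_halfband_analysis(7, omega_p = 0.9 * pi), "omega_p")
})

test_that("bank completion reconstructs and respects biorthogonal duality", {
  bank <- small_bank()
  x <- with(list(), { set.seed(11); rnorm(64) })
  ad <- analyze_one_level(x, bank)
  expect_lt(rel_err(synthesize_one_level(ad$approx, ad$detail, bank), x), 1e-10)
  # h1 signs alternate relative to f0 (modulation definition)
  expect_equal(abs(bank$h1$taps), abs(bank$f0$taps))
  s <- sign(bank$h1$taps * bank$f0$taps)
  expect_true(all(abs(diff(s[s != 0])) %in% c(0, 2)))
  # swap analysis and synthesis roles: the dual bank must also reconstruct
  dual <- bank
  dual$h0 <- bank$f0
  dual$f0 <- bank$h0
  n_h1 <- (bank$h0$lo:(bank$h0$lo + length(bank$h0$taps) - 1)) - 1
  dual$h1 <- list(taps = (-1)^(n_h1 + 1) * bank$h0$taps, lo = n_h1[1])
  n_f1 <- (bank$f0$lo:(bank$f0$lo + length(bank$f0$taps) - 1)) + 1
  dual$f1 <- list(taps = (-1)^(n_f1 + 1) * bank$f0$taps, lo = n_f1[1])
  ad2 <- analyze_one_level(x, dual)
  expect_lt(rel_err(synthesize_one_level(ad2$approx, ad2$detail, dual), x), 1e-10)
})

test_that("a lowpass pair violating PR is rejected by the bank self-test", {
  h0 <- maxflat_halfband(7)
  f_bad <- structure(c(0.1, 0.2, 0.4, 0.2, 0.1), class = "lp_filter")
  expect_error(make_filter_bank(h0, f_bad), "reconstruction self-test")
})

test_that("vanishing-moment counting matches direct moment evaluation", {
  expect_identical(vanishing_moments(c(1, 2, 1) / 4), 2L)
  expect_identical(vanishing_moments(c(0, 1, 0)), 0L)
  f0 <- design_synthesis_lowpass(maxflat_halfband(11), 13, V = 2)
  expect_gte(vanishing_moments(f0), 2)
})

test_that("time-frequency localization matches hand-computable cases", {
  expect_equal(tf_localization(c(0, 0, 1, 0, 0))$sigma_t2, 0)
  expect_equal(tf_localization(c(0.5, 0.5))$sigma_t2, 0.25)
  tl <- tf_localization(as.numeric(maxflat_halfband(7)))
  expect_gte(tl$product, 0)
  expect_error(tf_localization(numeric(3) * 0), "zero")
})

test_that("filter banks serialize to text and reload identically", {
  bank <- test_bank()
  path <- withr::local_tempfile(fileext = ".txt")
  write_filter_bank(bank, path)
  bank2 <- read_filter_bank(path)
  expect_identical(bank2$h0$taps, bank$h0$taps)
  expect_identical(bank2$f0$taps, bank$f0$taps)
  expect_identical(bank2$h1, bank$h1)
  expect_identical(bank2$f1, bank$f1)
  expect_identical(bank2$meta$L, bank$meta$L)
})
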