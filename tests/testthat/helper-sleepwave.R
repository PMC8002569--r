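# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# package-default bank (L = 11, M = 17)
test_bank <- function() memo("bank_default", default_filter_bank())

# smallest feasible bank: maxflat length-7 analysis, length-9 synthesis
small_bank <- function() memo("bank_small", {
  h0 <- maxflat_halfband(7)
  make_filter_bank(h0, design_synthesis_lowpass(h0, 9, V = 2))
})

# mean periodogram power of x in [lo, hi) Hz -- independent spectral oracle
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (0:(n - 1)) * fs / n
  sel <- f >= lo & f < hi & f <= fs / 2
  mean(p[sel])
}

# small labelled cohort at 128 Hz, one channel, reused by feature/tree tests
test_cohort <- function(n_per_stage = 30, seed = 42) {
  memo(sprintf("cohort_%d_%d", n_per_stage, seed), {
    spec <- cohort_spec(
      list(healthy = stats::setNames(rep(n_per_stage, 6), stage_levels())),
      fs = 128, epoch_s = 30, seed = seed, channels = "F4-C4")
    generate_cohort(spec)
  })
}

test_features <- function(n_per_stage = 30, seed = 42) {
  memo(sprintf("features_%d_%d", n_per_stage, seed), {
    build_feature_matrix(test_cohort(n_per_stage, seed), small_bank())
  })
}

rel_err <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}

# raw single-tree prediction, for comparing an ensemble against its members
.cart_predict_wrap <- function(tree, X) {
  getFromNamespace(".cart_predict", "sleepwave")(tree, X)
}
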