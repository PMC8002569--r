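# Stage-conditioned synthetic EEG.  Each stage has a spectral profile over
# the classical EEG bands; epochs are sums of band-limited Gaussian noise
# with the profile's relative band powers, scaled to a stage-specific RMS
# amplitude.  This emulates the qualitative spectral physiology of sleep
# (delta-dominant deep sleep with the largest amplitudes, alpha/beta wake,
# theta-dominant S1/REM) well enough to exercise every downstream stage of
# the scoring pipeline without real recordings.

eeg_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "sigma", "beta", "gamma"),
    lo = c(0.5, 4, 8, 12, 16, 32),
    hi = c(4, 8, 13, 16, 32, 64),
    stringsAsFactors = FALSE
  )
}

#' Default stage spectral profiles
#'
#' Relative band powers (delta 0.5--4 Hz, theta 4--8, alpha 8--13, sigma
#' 12--16, beta 16--32, gamma 32--64) and target RMS amplitude in microvolts
#' for each sleep stage.  The defaults encode the textbook physiology: wake is
#' alpha/beta dominant at low amplitude, S1 theta dominant, S2 adds spindle
#' (sigma) activity, S3/S4 are increasingly delta dominant with the largest
#' amplitudes, REM is mixed theta/beta at low amplitude.  Per-stage delta
#' power is strictly ordered S4 > S3 > S2 > REM.
#'
#' @return named list; each element has \code{band_weights} (named, summing
#'   to 1) and \code{amplitude_scale} (microvolt RMS).
#' @export
stage_profiles <- function() {
  w <- list(
    W   = c(delta = 0.10, theta = 0.10, alpha = 0.45, sigma = 0.05, beta = 0.25, gamma = 0.05),
    S1  = c(delta = 0.15, theta = 0.55, alpha = 0.10, sigma = 0.05, beta = 0.10, gamma = 0.05),
    S2  = c(delta = 0.25, theta = 0.35, alpha = 0.05, sigma = 0.25, beta = 0.08, gamma = 0.02),
    S3  = c(delta = 0.60, theta = 0.30, alpha = 0.03, sigma = 0.04, beta = 0.02, gamma = 0.01),
    S4  = c(delta = 0.85, theta = 0.10, alpha = 0.01, sigma = 0.02, beta = 0.01, gamma = 0.01),
    REM = c(delta = 0.12, theta = 0.45, alpha = 0.08, sigma = 0.05, beta = 0.25, gamma = 0.05)
  )
  amp <- c(W = 30, S1 = 40, S2 = 50, S3 = 65, S4 = 80, REM = 35)
  out <- lapply(stage_levels(), function(s) {
    list(stage = s, band_weights = w[[s]], amplitude_scale = unname(amp[s]))
  })
  names(out) <- stage_levels()
  out
}

validate_profile <- function(p) {
  bw <- p$band_weights
  if (any(bw < 0) || !any(bw > 0)) {
    stop("band_weights must be non-negative with at least one positive entry",
         call. = FALSE)
  }
  if (!is.numeric(p$amplitude_scale) || p$amplitude_scale <= 0) {
    stop("amplitude_scale must be positive", call. = FALSE)
  }
  invisible(p)
}

#' Generate one synthetic EEG epoch
#'
#' Synthesizes \code{fs * epoch_s} samples as a sum of band-limited Gaussian
#' noise components: in the frequency domain, each EEG band receives complex
#' Gaussian coefficients whose total power matches the stage's relative band
#' weight; the real signal is then scaled to the stage's RMS amplitude.
#' Bit-identical output for identical \code{(stage, fs, epoch_s, seed)}.
#'
#' @param stage a stage label from [stage_levels()].
#' @param fs sampling rate in Hz (\code{>= 128}).
#' @param epoch_s epoch duration in seconds.
#' @param seed integer stream seed.
#' @param profiles stage profiles as from [stage_profiles()].
#' @return numeric vector of length \code{fs * epoch_s} (microvolts).
#' @export
#' @examples
#' x <- generate_epoch("S4", fs = 512, epoch_s = 30, seed = 1)
#' length(x)
generate_epoch <- function(stage, fs = 512, epoch_s = 30, seed = 1L,
                           profiles = stage_profiles()) {
  stage <- as.character(stage)
  if (!stage %in% names(profiles)) {
    stop(sprintf("unknown stage label '%s'; expected one of %s",
                 stage, paste(names(profiles), collapse = ", ")), call. = FALSE)
  }
  if (fs < 128) stop("fs must be >= 128 Hz", call. = FALSE)
  if (epoch_s <= 0) stop("epoch_s must be positive", call. = FALSE)
  prof <- validate_profile(profiles[[stage]])
  n <- as.integer(round(fs * epoch_s))
  bands <- eeg_bands()
  half <- (n - 1L) %/% 2L                  # strictly positive frequencies
  freq <- (1:half) * fs / n
  spec <- complex(half)
  with_seed(seed, {
    for (b in seq_len(nrow(bands))) {
      w <- prof$band_weights[[bands$band[b]]]
      idx <- which(freq > bands$lo[b] & freq <= bands$hi[b])
      if (!length(idx) || w == 0) next
      amp <- sqrt(w / length(idx))
      spec[idx] <- spec[idx] +
        amp * complex(real = stats::rnorm(length(idx)),
                      imaginary = stats::rnorm(length(idx)))
    }
  })
  full <- complex(n)
  full[2:(half + 1L)] <- spec
  full[n:(n - half + 1L)] <- Conj(spec)
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  rms <- sqrt(mean(x^2))
  if (rms == 0) stop("degenerate profile produced a zero signal", call. = FALSE)
  x * prof$amplitude_scale / rms
}

#' Specify a synthetic cohort
#'
#' @param groups named list: one entry per group, each a named count vector
#'   over the six stages (missing stages count 0).
#' @param fs sampling rate in Hz.
#' @param epoch_s epoch length in seconds.
#' @param seed master seed; per-epoch streams are derived from
#'   \code{(seed, group, stage, index, channel)} so cohorts are
#'   order-independent.
#' @param channels channel names to synthesize.
#' @return object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(groups, fs = 512, epoch_s = 30, seed = 1L,
                        channels = c("F4-C4", "C4-A1")) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  groups <- lapply(groups, function(cnt) {
    full <- stats::setNames(rep(0L, 6L), stage_levels())
    if (length(cnt)) {
      if (is.null(names(cnt))) {
        if (length(cnt) != 6L) stop("unnamed counts must have length 6", call. = FALSE)
        names(cnt) <- stage_levels()
      }
      bad <- setdiff(names(cnt), stage_levels())
      if (length(bad)) stop("unknown stages in counts: ", paste(bad, collapse = ", "),
                            call. = FALSE)
      full[names(cnt)] <- as.integer(cnt)
    }
    if (any(full < 0)) stop("epoch counts must be >= 0", call. = FALSE)
    full
  })
  if (fs <= 0 || epoch_s <= 0) stop("fs and epoch_s must be positive", call. = FALSE)
  structure(list(groups = groups, fs = fs, epoch_s = epoch_s,
                 seed = as.integer(seed), channels = channels),
            class = "cohort_spec")
}

# per-channel gain emulating the larger unipolar (C4-A1) amplitudes relative
# to the bipolar derivation
channel_gain <- function(channel) {
  if (toupper(gsub("\\s", "", channel)) == "C4-A1") 2.0 else 1.0
}

#' Generate a synthetic labelled cohort
#'
#' Produces exactly the requested number of epochs per (group, stage), each
#' with all channels of the spec, labels attached, reproducible from the
#' master seed.
#'
#' @param spec a [cohort_spec()].
#' @param profiles stage profiles (see [stage_profiles()]).
#' @return an \code{"epoch_set"} (see [epoch_set()]).
#' @export
generate_cohort <- function(spec, profiles = stage_profiles()) {
  stopifnot(inherits(spec, "cohort_spec"))
  records <- list()
  for (g in names(spec$groups)) {
    counts <- spec$groups[[g]]
    idx_in_group <- 0L
    for (s in stage_levels()) {
      nse <- counts[[s]]
      if (nse == 0L) next
      for (i in seq_len(nse)) {
        samples <- lapply(spec$channels, function(ch) {
          sd <- derive_seed(spec$seed, g, s, i, ch)
          channel_gain(ch) * generate_epoch(s, fs = spec$fs,
                                            epoch_s = spec$epoch_s,
                                            seed = sd, profiles = profiles)
        })
        names(samples) <- spec$channels
        records[[length(records) + 1L]] <- list(
          samples = samples, label = s,
          subject_id = paste0("syn-", g, "-1"), group = g,
          epoch_index = idx_in_group)
        idx_in_group <- idx_in_group + 1L
      }
    }
  }
  epoch_set(records, channels = spec$channels, fs = spec$fs,
            epoch_s = spec$epoch_s)
}

#' Write a synthetic cohort as EDF plus hypnogram text
#'
#' One EDF file and one hypnogram per (synthetic) subject, concatenating that
#' subject's epochs in order, to exercise the real readers end to end.
#'
#' @param set an \code{"epoch_set"}.
#' @param dir output directory (created if missing).
#' @return invisibly, a data.frame with the written file paths per subject.
#' @export
write_cohort_edf <- function(set, dir) {
  stopifnot(inherits(set, "epoch_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  subjects <- unique(vapply(set$records, `[[`, "", "subject_id"))
  out <- lapply(subjects, function(sub) {
    recs <- Filter(function(r) r$subject_id == sub, set$records)
    sig <- lapply(set$channels, function(ch) {
      unlist(lapply(recs, function(r) r$samples[[ch]]), use.names = FALSE)
    })
    names(sig) <- set$channels
    edf <- file.path(dir, paste0(sub, ".edf"))
    hyp <- file.path(dir, paste0(sub, ".txt"))
    write_edf(edf, sig, fs = set$fs, record_s = set$epoch_s,
              patient = sub, recording = "synthetic sleep EEG")
    write_hypnogram(hyp, vapply(recs, `[[`, "", "label"),
                    epoch_s = set$epoch_s)
    data.frame(subject = sub, edf = edf, hypnogram = hyp,
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, out))
}
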