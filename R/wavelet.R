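# Five-level 1-D wavelet decomposition of 30-s EEG epochs with periodic
# boundary handling.  Periodic extension keeps perfect reconstruction exact
# and the subband bookkeeping deterministic: an epoch of 15,360 samples
# (30 s at 512 Hz) halves cleanly through all five levels.

# circular convolution of x with a filter given as taps on support
# n = lo, ..., lo + length(taps) - 1 (zero-phase bookkeeping)
circular_filter <- function(x, filt) {
  N <- length(x)
  if (length(filt$taps) > N) {
    stop(sprintf("input of length %d is shorter than the filter (%d taps)",
                 N, length(filt$taps)), call. = FALSE)
  }
  kern <- numeric(N)
  n <- (filt$lo + seq_along(filt$taps) - 1L) %% N
  for (i in seq_along(filt$taps)) {
    kern[n[i] + 1L] <- kern[n[i] + 1L] + filt$taps[i]
  }
  Re(stats::fft(stats::fft(x) * stats::fft(kern), inverse = TRUE)) / N
}

#' One analysis level of the two-channel filter bank
#'
#' Filters the input with the analysis lowpass and highpass (periodic
#' extension) and keeps the even-indexed samples of each full-rate output.
#'
#' @param x numeric sample vector of even length, at least as long as the
#'   longest analysis filter.
#' @param bank a \code{"wavelet_filter_bank"} ([make_filter_bank()]).
#' @return list with \code{approx} and \code{detail}, each of length
#'   \code{length(x)/2}.
#' @export
analyze_one_level <- function(x, bank) {
  N <- length(x)
  if (N %% 2L != 0L) {
    stop("periodic analysis requires an even-length input", call. = FALSE)
  }
  keep <- seq(1L, N, by = 2L)      # samples n = 0, 2, 4, ...
  list(approx = circular_filter(x, bank$h0)[keep],
       detail = circular_filter(x, bank$h1)[keep])
}

#' One synthesis level of the two-channel filter bank
#'
#' Upsamples the two subbands by two and filters with the synthesis pair;
#' exact inverse of [analyze_one_level()] for a perfect-reconstruction bank.
#'
#' @param approx,detail coefficient vectors of equal length.
#' @param bank a \code{"wavelet_filter_bank"}.
#' @return numeric vector of length \code{2 * length(approx)}.
#' @export
synthesize_one_level <- function(approx, detail, bank) {
  if (length(approx) != length(detail)) {
    stop("approximation and detail bands must have equal length", call. = FALSE)
  }
  N <- 2L * length(approx)
  v0 <- numeric(N); v0[seq(1L, N, by = 2L)] <- approx
  v1 <- numeric(N); v1[seq(1L, N, by = 2L)] <- detail
  circular_filter(v0, bank$f0) + circular_filter(v1, bank$f1)
}

#' Multilevel wavelet decomposition into J + 1 sub-bands
#'
#' Iterates [analyze_one_level()] on the approximation \code{J} times.  With
#' the default \code{J = 5} a 30-s epoch yields six sub-bands Sb-1..Sb-6,
#' ordered coarsest first: Sb-1 is the level-5 approximation (0--8 Hz at
#' 512 Hz), Sb-2 the level-5 detail (8--16 Hz), ..., Sb-6 the level-1 detail
#' (128--256 Hz).
#'
#' @param x numeric epoch samples; \code{length(x)} must be divisible by
#'   \code{2^J}.
#' @param bank a \code{"wavelet_filter_bank"}.
#' @param J number of decomposition levels (default 5).
#' @param fs sampling rate in Hz, carried as metadata.
#' @return object of class \code{"subband_set"}: list with \code{bands}
#'   (list Sb-1..Sb-6), \code{level_map}, \code{J} and \code{fs}.
#' @export
wavedec <- function(x, bank, J = 5L, fs = NA_real_) {
  J <- as.integer(J)
  if (J < 1L) stop("J must be >= 1", call. = FALSE)
  if (length(x) %% (2^J) != 0L) {
    stop(sprintf("signal length %d is not divisible by 2^%d; cannot decompose",
                 length(x), J), call. = FALSE)
  }
  if (length(x) / 2^J < 1L) stop("J too large for this signal", call. = FALSE)
  details <- vector("list", J)
  a <- x
  for (lev in seq_len(J)) {
    ad <- analyze_one_level(a, bank)
    details[[lev]] <- ad$detail
    a <- ad$approx
  }
  bands <- c(list(a), rev(details))
  names(bands) <- paste0("Sb-", seq_len(J + 1L))
  level_map <- data.frame(
    band = names(bands),
    level = c(J, J:1),
    type = c("approx", rep("detail", J)),
    stringsAsFactors = FALSE
  )
  structure(list(bands = bands, level_map = level_map, J = J, fs = fs),
            class = "subband_set")
}

#' Inverse multilevel wavelet transform
#'
#' @param s a \code{"subband_set"} from [wavedec()].
#' @param bank the \code{"wavelet_filter_bank"} used for analysis.
#' @return reconstructed sample vector.
#' @export
waverec <- function(s, bank) {
  stopifnot(inherits(s, "subband_set"))
  J <- s$J
  a <- s$bands[[1L]]
  for (lev in J:1) {
    d <- s$bands[[J + 2L - lev]]
    if (length(d) != length(a)) {
      stop(sprintf("band length mismatch at level %d (%d approx vs %d detail)",
                   lev, length(a), length(d)), call. = FALSE)
    }
    a <- synthesize_one_level(a, d, bank)
  }
  a
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("Subband set: %d levels, %d bands (fs = %s Hz)\n",
              x$J, length(x$bands), format(x$fs)))
  cat("  lengths:", paste(vapply(x$bands, length, 1L), collapse = ", "), "\n")
  invisible(x)
}
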