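# Minimal EDF (European Data Format) reader and writer: standard 256-byte
# header, 256 bytes per signal, 16-bit little-endian samples with the
# header's digital-to-physical affine mapping.  Covers plain EDF as used for
# sleep EEG exports; EDF+ annotation streams are out of scope.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

fmt_num8 <- function(x) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  if (nchar(s) > 8) s <- formatC(x, format = "g", digits = 4, width = -1)
  pad_field(s, 8)
}

#' Write signals to an EDF file
#'
#' @param path output file path.
#' @param signals named list of numeric vectors (physical units, e.g.
#'   microvolts), all the same length; names become channel labels.
#' @param fs sampling rate in Hz (shared by all signals).
#' @param record_s data-record duration in seconds; the signal length must be
#'   a whole number of records.
#' @param patient,recording free-text header fields.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(path, signals, fs, record_s = 1,
                      patient = "X", recording = "sleepwave export") {
  stopifnot(is.list(signals), length(signals) >= 1, !is.null(names(signals)))
  ns <- length(signals)
  len <- unique(vapply(signals, length, 1L))
  if (length(len) != 1L) stop("all signals must have the same length", call. = FALSE)
  spr <- as.integer(round(fs * record_s))     # samples per record per signal
  if (len %% spr != 0L) {
    stop(sprintf("signal length %d is not a whole number of %g-s records at %g Hz",
                 len, record_s, fs), call. = FALSE)
  }
  nrec <- len %/% spr
  dmin <- -32768L; dmax <- 32767L
  # integer physical bounds: exactly representable in the 8-char ascii
  # fields, so encoding and decoding use identical scaling and the
  # roundtrip error stays within half a quantization step
  pmins <- vapply(signals, function(x) floor(min(x)), 1)
  pmaxs <- vapply(signals, function(x) ceiling(max(x)), 1)
  flat <- pmaxs - pmins < 1
  pmins[flat] <- pmins[flat] - 1
  pmaxs[flat] <- pmaxs[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr(patient, 80)
  wr(recording, 80)
  wr(format(Sys.Date(), "01.01.20"), 8)     # fixed nominal start date/time:
  wr("00.00.00", 8)                         # synthetic records are undated
  wr(as.character(256L * (ns + 1L)), 8)
  wr("", 44)
  wr(as.character(nrec), 8)
  wr(formatC(record_s, format = "g", width = -1), 8)
  wr(as.character(ns), 4)
  for (nm in names(signals)) wr(nm, 16)
  for (i in seq_len(ns)) wr("synthetic", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) writeChar(fmt_num8(pmins[i]), con, nchars = 8, eos = NULL)
  for (i in seq_len(ns)) writeChar(fmt_num8(pmaxs[i]), con, nchars = 8, eos = NULL)
  for (i in seq_len(ns)) wr(as.character(dmin), 8)
  for (i in seq_len(ns)) wr(as.character(dmax), 8)
  for (i in seq_len(ns)) wr("none", 80)
  for (i in seq_len(ns)) wr(as.character(spr), 8)
  for (i in seq_len(ns)) wr("", 32)
  # re-read the header's 8-char physical bounds so scaling matches exactly
  pmin_hdr <- as.numeric(vapply(pmins, fmt_num8, ""))
  pmax_hdr <- as.numeric(vapply(pmaxs, fmt_num8, ""))
  scale <- (pmax_hdr - pmin_hdr) / (dmax - dmin)
  digital <- lapply(seq_len(ns), function(i) {
    d <- round((signals[[i]] - pmin_hdr[i]) / scale[i]) + dmin
    as.integer(pmin(pmax(d, dmin), dmax))
  })
  for (r in seq_len(nrec)) {
    sel <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(ns)) {
      writeBin(digital[[i]][sel], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

norm_label <- function(x) toupper(gsub("\\s+", "", x))

read_edf_header <- function(con) {
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  h <- list()
  h$version <- rd(8)
  h$patient <- rd(80)
  h$recording <- rd(80)
  h$startdate <- rd(8)
  h$starttime <- rd(8)
  h$header_bytes <- as.integer(rd(8))
  rd(44)
  h$n_records <- as.integer(rd(8))
  h$record_s <- as.numeric(rd(8))
  h$ns <- as.integer(rd(4))
  if (is.na(h$ns) || h$ns < 1L || is.na(h$n_records) || is.na(h$record_s)) {
    stop("malformed EDF header", call. = FALSE)
  }
  ns <- h$ns
  h$labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)            # transducer
  h$dim <- vapply(seq_len(ns), function(i) rd(8), "")
  h$pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  h$pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  h$dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  h$dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)            # prefiltering
  h$spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (anyNA(c(h$pmin, h$pmax, h$dmin, h$dmax, h$spr))) {
    stop("malformed EDF header (signal fields)", call. = FALSE)
  }
  h
}

#' Read one channel from an EDF file
#'
#' Channel matching is case-insensitive and whitespace-normalized.  Samples
#' are converted to physical units with the header's digital-to-physical
#' mapping; the sampling rate is derived from the header.
#'
#' @param path EDF file path.
#' @param channel_name channel label, e.g. \code{"F4-C4"}.
#' @return list with \code{samples} (numeric, physical units) and \code{fs}
#'   (Hz).
#' @export
read_edf_channel <- function(path, channel_name) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  idx <- match(norm_label(channel_name), norm_label(h$labels))
  if (is.na(idx)) {
    stop(sprintf("channel '%s' not found; available channels: %s",
                 channel_name, paste(h$labels, collapse = ", ")), call. = FALSE)
  }
  scale <- (h$pmax[idx] - h$pmin[idx]) / (h$dmax[idx] - h$dmin[idx])
  spr <- h$spr
  out <- numeric(h$n_records * spr[idx])
  pos <- 0L
  for (r in seq_len(h$n_records)) {
    for (i in seq_len(h$ns)) {
      vals <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                      endian = "little")
      if (i == idx) {
        out[(pos + 1L):(pos + spr[i])] <- (vals - h$dmin[i]) * scale + h$pmin[i]
        pos <- pos + spr[i]
      }
    }
  }
  list(samples = out, fs = spr[idx] / h$record_s)
}
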