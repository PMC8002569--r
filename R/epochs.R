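# Labelled 30-s epochs and their accounting.

#' Construct an epoch set
#'
#' An epoch set is an ordered collection of labelled epochs sharing a channel
#' set and sampling rate.  Each record holds per-channel sample vectors of
#' length \code{fs * epoch_s}, a stage label, subject id, group and epoch
#' index.
#'
#' @param records list of records (see Details in [generate_cohort()] /
#'   [segment_epochs()]).
#' @param channels ordered channel names.
#' @param fs sampling rate in Hz.
#' @param epoch_s epoch duration in seconds.
#' @return object of class \code{"epoch_set"}.
#' @export
epoch_set <- function(records, channels, fs, epoch_s = 30) {
  n <- as.integer(round(fs * epoch_s))
  for (r in records) {
    if (!all(channels %in% names(r$samples))) {
      stop("every record must carry all channels of the set", call. = FALSE)
    }
    if (any(vapply(r$samples[channels], length, 1L) != n)) {
      stop(sprintf("every sample vector must have length fs * epoch_s = %d", n),
           call. = FALSE)
    }
    if (!r$label %in% stage_levels()) {
      stop(sprintf("invalid stage label '%s'", r$label), call. = FALSE)
    }
  }
  structure(list(records = records, channels = channels, fs = fs,
                 epoch_s = epoch_s),
            class = "epoch_set")
}

#' @export
length.epoch_set <- function(x) length(x$records)

#' Stage labels of an epoch set
#'
#' @param set an \code{"epoch_set"}.
#' @return factor over [stage_levels()].
#' @export
epoch_labels <- function(set) {
  stage_factor(vapply(set$records, `[[`, "", "label"))
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set: %d epochs x %d channel(s) [%s], fs = %g Hz, %g s\n",
              length(x$records), length(x$channels),
              paste(x$channels, collapse = ", "), x$fs, x$epoch_s))
  if (length(x$records)) print(table(epoch_labels(x)))
  invisible(x)
}

#' Segment continuous signals into labelled epochs
#'
#' One record per scored epoch fully covered by the signal; trailing epochs
#' that run past the end of the recording are dropped (with a message).
#' Epochs start at the hypnogram onsets, not at a fixed grid.
#'
#' @param samples named list of per-channel sample vectors, all equal length.
#' @param fs sampling rate in Hz.
#' @param hypnogram data.frame with \code{onset_s} and \code{stage} (from
#'   [parse_hypnogram()]), or a character vector of labels scored every
#'   \code{epoch_s} seconds from time 0.
#' @param subject_id,group metadata attached to each record.
#' @param epoch_s epoch duration in seconds.
#' @return an \code{"epoch_set"}.
#' @export
segment_epochs <- function(samples, fs, hypnogram, subject_id = "subject",
                           group = NA_character_, epoch_s = 30) {
  stopifnot(is.list(samples), length(samples) >= 1, !is.null(names(samples)))
  lens <- vapply(samples, length, 1L)
  if (length(unique(lens)) != 1L) {
    stop("all channels must have the same length", call. = FALSE)
  }
  nsig <- lens[[1]]
  if (is.character(hypnogram)) {
    hypnogram <- data.frame(onset_s = (seq_along(hypnogram) - 1) * epoch_s,
                            stage = hypnogram, stringsAsFactors = FALSE)
  }
  n <- as.integer(round(fs * epoch_s))
  records <- list()
  dropped <- 0L
  if (nrow(hypnogram)) {
    for (i in seq_len(nrow(hypnogram))) {
      start <- as.integer(round(hypnogram$onset_s[i] * fs))
      if (start < 0L || start + n > nsig) { dropped <- dropped + 1L; next }
      lab <- normalize_stage(hypnogram$stage[i])
      if (is.na(lab)) { dropped <- dropped + 1L; next }
      records[[length(records) + 1L]] <- list(
        samples = lapply(samples, function(x) x[(start + 1L):(start + n)]),
        label = lab, subject_id = subject_id, group = group,
        epoch_index = length(records))
    }
  }
  if (dropped > 0) {
    message(sprintf("segment_epochs: dropped %d epoch(s) not fully covered or unscored",
                    dropped))
  }
  epoch_set(records, channels = names(samples), fs = fs, epoch_s = epoch_s)
}

#' Epoch accounting across groups
#'
#' Per-group, per-stage epoch counts with stage totals and each stage's
#' percentage of the grand total (two decimals), in the layout of the study's
#' epoch-distribution tables.
#'
#' @param sets named list mapping group name to \code{"epoch_set"}.
#' @return see [accounting_table()].
#' @export
epoch_accounting <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1, !is.null(names(sets)))
  counts <- vapply(sets, function(s) {
    as.integer(table(epoch_labels(s)))
  }, integer(6))
  rownames(counts) <- stage_levels()
  accounting_table(counts)
}

#' Accounting table from a stage-by-group count matrix
#'
#' @param counts integer matrix, rows = the six stages, columns = groups.
#' @return data.frame with one row per stage plus a \code{Total} row; columns
#'   are the groups, \code{Total} and \code{Percent} (stage share of the
#'   grand total, rounded to 2 decimals).
#' @export
accounting_table <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 6L) stop("counts must have six stage rows", call. = FALSE)
  rownames(counts) <- stage_levels()
  stage_tot <- rowSums(counts)
  grand <- sum(stage_tot)
  pct <- if (grand > 0) round(100 * stage_tot / grand, 2) else rep(NA_real_, 6)
  out <- data.frame(counts, Total = stage_tot, Percent = pct,
                    check.names = FALSE)
  out <- rbind(out, Total = c(colSums(counts), grand, NA))
  out
}
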