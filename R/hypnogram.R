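# Plain-text hypnogram support.  Scorer exports vary; the supported dialect
# is a delimited table with a header naming a stage column ("Sleep Stage"),
# an onset column (numeric "Position" in seconds, or "Time [hh:mm:ss]"
# clock time relative to the first scored epoch) and an optional
# "Duration[s]" column; 30-s scoring is assumed unless the duration column
# says otherwise.

#' Write a hypnogram text file
#'
#' @param path output path.
#' @param stages character vector of stage labels, one per epoch, in order.
#' @param epoch_s epoch duration in seconds.
#' @param start_s onset of the first epoch in seconds.
#' @return \code{path}, invisibly.
#' @export
write_hypnogram <- function(path, stages, epoch_s = 30, start_s = 0) {
  onset <- start_s + (seq_along(stages) - 1) * epoch_s
  lines <- c("Sleep Stage\tPosition\tDuration[s]",
             sprintf("%s\t%g\t%g", as.character(stages), onset, epoch_s))
  writeLines(lines, path)
  invisible(path)
}

parse_clock <- function(x) {
  parts <- strsplit(trimws(x), "[:.]")
  vapply(parts, function(p) {
    if (length(p) != 3L || anyNA(suppressWarnings(as.numeric(p)))) return(NA_real_)
    as.numeric(p[1]) * 3600 + as.numeric(p[2]) * 60 + as.numeric(p[3])
  }, numeric(1))
}

#' Parse a hypnogram
#'
#' Returns one entry per scored 30-s epoch, ordered by onset.  Labels are
#' mapped onto the canonical six (\code{R} and \code{REM} both mean REM);
#' unscored labels such as \code{MT} are dropped with a message giving the
#' count.  Clock times are interpreted relative to the first entry, with a
#' single midnight wrap allowed.
#'
#' @param x a file path, or a character vector of lines.
#' @param stage_col,time_col,duration_col header names; \code{time_col = NULL}
#'   auto-detects \code{"Position"} then \code{"Time [hh:mm:ss]"}.
#' @return data.frame with \code{onset_s} and \code{stage}.
#' @export
parse_hypnogram <- function(x, stage_col = "Sleep Stage", time_col = NULL,
                            duration_col = "Duration[s]") {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(data.frame(onset_s = numeric(0),
                                        stage = character(0)))
  delim <- if (any(grepl("\t", lines[1]))) "\t" else "[,;]"
  split1 <- function(l) trimws(strsplit(l, delim)[[1]])
  header_at <- which(vapply(lines, function(l) stage_col %in% split1(l),
                            logical(1)))[1]
  if (is.na(header_at)) {
    stop(sprintf("no header row with a '%s' column found", stage_col),
         call. = FALSE)
  }
  header <- split1(lines[header_at])
  si <- match(stage_col, header)
  if (is.null(time_col)) {
    time_col <- intersect(c("Position", "Time [hh:mm:ss]"), header)[1]
    if (is.na(time_col)) {
      stop("no onset column found (expected 'Position' or 'Time [hh:mm:ss]')",
           call. = FALSE)
    }
  }
  ti <- match(time_col, header)
  body_idx <- seq.int(header_at + 1L, length(lines))
  if (header_at == length(lines)) body_idx <- integer(0)
  onset <- numeric(0); stage_raw <- character(0)
  for (j in body_idx) {
    f <- split1(lines[j])
    if (length(f) < max(si, ti)) {
      stop(sprintf("hypnogram line %d cannot be parsed: '%s'", j, lines[j]),
           call. = FALSE)
    }
    t <- suppressWarnings(as.numeric(f[ti]))
    if (is.na(t)) t <- parse_clock(f[ti])
    if (is.na(t)) {
      stop(sprintf("hypnogram line %d has an unparseable onset '%s'", j, f[ti]),
           call. = FALSE)
    }
    onset <- c(onset, t)
    stage_raw <- c(stage_raw, f[si])
  }
  if (time_col != "Position" && length(onset)) {
    # clock time: rebase on the first entry, allow one midnight wrap
    onset <- onset - onset[1]
    wrap <- which(diff(onset) < 0)
    if (length(wrap)) onset[(wrap[1] + 1L):length(onset)] <-
        onset[(wrap[1] + 1L):length(onset)] + 86400
  }
  stage <- normalize_stage(stage_raw)
  dropped <- sum(is.na(stage))
  if (dropped > 0) {
    message(sprintf("parse_hypnogram: dropped %d unscored/unknown epoch label(s)",
                    dropped))
  }
  keep <- !is.na(stage)
  out <- data.frame(onset_s = onset[keep], stage = stage[keep],
                    stringsAsFactors = FALSE)
  out[order(out$onset_s), , drop = FALSE]
}
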