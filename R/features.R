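# Sub-band norm features: l1, l2 and l-infinity norms of the six wavelet
# sub-bands, 18 features per channel, concatenated across channels.

#' Vector m-norm
#'
#' \eqn{\|u\|_m = (\sum_n |u[n]|^m)^{1/m}} for a positive integer \code{m};
#' the empty vector returns 0 by convention.
#'
#' @param u numeric coefficient vector.
#' @param m positive integer order (the pipeline uses 1 and 2).
#' @return scalar \code{>= 0}.
#' @export
#' @examples
#' lm_norm(c(3, -4), 1)  # 7
#' lm_norm(c(3, -4), 2)  # 5
lm_norm <- function(u, m) {
  stopifnot(is.numeric(m), length(m) == 1L, m >= 1)
  if (!length(u)) {
    message("lm_norm: empty vector, returning 0")
    return(0)
  }
  sum(abs(u)^m)^(1 / m)
}

#' Peak absolute value (l-infinity norm)
#'
#' @param u numeric coefficient vector.
#' @return \code{max(abs(u))}; 0 for an empty vector.
#' @export
linf_norm <- function(u) {
  if (!length(u)) {
    message("linf_norm: empty vector, returning 0")
    return(0)
  }
  max(abs(u))
}

subband_feature_names <- function(channel, J = 5L) {
  as.vector(t(outer(paste0(channel, "_Sb", seq_len(J + 1L)),
                    c("l1", "l2", "linf"), paste, sep = "_")))
}

#' Norm features of one epoch
#'
#' Decomposes each requested channel into \code{J + 1} sub-bands and computes
#' the l1, l2 and l-infinity norm of each: 18 features per channel for
#' \code{J = 5}, concatenated over channels (36 for the two-channel
#' combination).
#'
#' @param epoch one epoch record (element of an \code{"epoch_set"}).
#' @param bank a \code{"wavelet_filter_bank"}.
#' @param channels channels to use (must be present in the epoch).
#' @param J decomposition levels.
#' @return named numeric vector with names
#'   \code{"{channel}_Sb{i}_{l1|l2|linf}"}.
#' @export
epoch_features <- function(epoch, bank, channels, J = 5L) {
  missing_ch <- setdiff(channels, names(epoch$samples))
  if (length(missing_ch)) {
    stop(sprintf("epoch lacks channel(s): %s", paste(missing_ch, collapse = ", ")),
         call. = FALSE)
  }
  out <- unlist(lapply(channels, function(ch) {
    sb <- wavedec(epoch$samples[[ch]], bank, J = J)
    vals <- unlist(lapply(sb$bands, function(u) {
      c(lm_norm(u, 1), lm_norm(u, 2), linf_norm(u))
    }), use.names = FALSE)
    stats::setNames(vals, subband_feature_names(ch, J))
  }))
  out
}

#' Build the epoch-by-feature matrix
#'
#' One row per epoch in input order, feature columns as in
#' [epoch_features()], plus \code{label}, \code{group} and \code{subject}
#' metadata columns.
#'
#' @param set an \code{"epoch_set"}.
#' @param bank a \code{"wavelet_filter_bank"}.
#' @param channels channels to use (default: all channels of the set).
#' @param J decomposition levels.
#' @return data.frame of class \code{"feature_matrix"}; feature column names
#'   are stored in \code{attr(, "feature_names")}.
#' @export
build_feature_matrix <- function(set, bank, channels = set$channels, J = 5L) {
  fn <- unlist(lapply(channels, subband_feature_names, J = J))
  if (!length(set$records)) {
    out <- as.data.frame(matrix(numeric(0), 0, length(fn),
                                dimnames = list(NULL, fn)),
                         check.names = FALSE)
    out$label <- factor(character(0), levels = stage_levels())
    out$group <- character(0)
    out$subject <- character(0)
    return(structure(out, feature_names = fn,
                     class = c("feature_matrix", "data.frame")))
  }
  feats <- t(vapply(set$records, epoch_features, numeric(length(fn)),
                    bank = bank, channels = channels, J = J))
  out <- as.data.frame(feats, check.names = FALSE)
  out$label <- epoch_labels(set)
  out$group <- vapply(set$records, function(r) as.character(r$group), "")
  out$subject <- vapply(set$records, `[[`, "", "subject_id")
  structure(out, feature_names = fn,
            class = c("feature_matrix", "data.frame"))
}

feature_names <- function(m) {
  fn <- attr(m, "feature_names")
  if (is.null(fn)) setdiff(names(m), c("label", "group", "subject")) else fn
}

feature_values <- function(m) {
  as.matrix(m[, feature_names(m), drop = FALSE])
}

#' Write / read a feature matrix as CSV
#'
#' @param m a \code{"feature_matrix"}.
#' @param path CSV path; a header row carries the feature names plus the
#'   \code{label}, \code{group} and \code{subject} columns.
#' @return \code{read_feature_matrix} returns the \code{"feature_matrix"}.
#' @export
write_feature_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  df$label <- stage_factor(df$label)
  structure(df, feature_names = setdiff(names(df), c("label", "group", "subject")),
            class = c("feature_matrix", "data.frame"))
}
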