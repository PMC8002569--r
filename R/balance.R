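# Class balancing by resampling: minority classes are grown by random
# over-sampling with replacement (exact duplicates of existing epochs, not
# synthesized ones), majority classes shrunk by random under-sampling
# without replacement, until every class holds the same number of epochs.

balance_indices <- function(labels, target_per_class, seed) {
  labels <- stage_factor(labels)
  target_per_class <- as.integer(target_per_class)
  if (target_per_class < 1L) stop("target_per_class must be >= 1", call. = FALSE)
  counts <- table(labels)
  absent <- names(counts)[counts == 0]
  if (length(absent)) {
    stop(sprintf("cannot balance: class(es) absent from input: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  with_seed(seed, {
    unlist(lapply(stage_levels(), function(s) {
      idx <- which(labels == s)
      n <- length(idx)
      if (n == target_per_class) {
        idx
      } else if (n > target_per_class) {
        sort(sample(idx, target_per_class, replace = FALSE))
      } else {
        c(idx, sample(idx, target_per_class - n, replace = TRUE))
      }
    }), use.names = FALSE)
  })
}

#' Equalize class counts by over- and under-sampling
#'
#' Every class ends with exactly \code{target_per_class} members: classes
#' above the target are randomly under-sampled without replacement, classes
#' below it keep all originals and add uniform draws with replacement.
#' Selection is deterministic given \code{seed}.  This resamples existing
#' rows only; no synthetic interpolation.
#'
#' @param x a \code{"feature_matrix"} (or any data.frame with a \code{label}
#'   column) or an \code{"epoch_set"}.
#' @param target_per_class target epochs per class.
#' @param seed integer seed.
#' @return the balanced object, same type as \code{x}.
#' @export
balance_classes <- function(x, target_per_class, seed = 1L) {
  UseMethod("balance_classes")
}

#' @export
balance_classes.data.frame <- function(x, target_per_class, seed = 1L) {
  if (is.null(x$label)) stop("input needs a 'label' column", call. = FALSE)
  idx <- balance_indices(x$label, target_per_class, seed)
  out <- x[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "feature_names") <- attr(x, "feature_names")
  class(out) <- class(x)
  out
}

#' @export
balance_classes.epoch_set <- function(x, target_per_class, seed = 1L) {
  labels <- as.character(epoch_labels(x))
  idx <- balance_indices(labels, target_per_class, seed)
  epoch_set(x$records[idx], channels = x$channels, fs = x$fs,
            epoch_s = x$epoch_s)
}
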