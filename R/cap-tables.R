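# Published reference tables of the CAP sleep database cohort (80 subjects,
# 80,667 scored 30-s epochs): per-group per-stage epoch counts, the balanced
# per-group targets, the repeated-CV trial accuracies of the healthy subset,
# and two row-percent confusion tables with their true-class totals.  These
# are inputs for worked metric arithmetic and for emulating the cohort's
# class imbalance; they are data, not computed results.

#' Epoch distribution of the CAP sleep cohort (unbalanced)
#'
#' Stage-by-group epoch counts: six stages by eight groups (healthy plus
#' seven sleep disorders), grand total 80,667.
#'
#' @return integer matrix, rows [stage_levels()], columns [group_levels()].
#' @export
cap_epoch_counts <- function() {
  m <- rbind(
    W   = c(445,  3801,  44, 1303,  3155, 1332,  5266,  495),
    S1  = c(280,   223,  34,  301,  1098,  266,  1048,  269),
    S2  = c(2172, 2456, 144, 1708, 10630, 2748,  7446, 1324),
    S3  = c(573,   670,  39,  476,  2987,  955,  2880,  224),
    S4  = c(1184,  415,  99,  568,  4108,  956,  2506,  352),
    REM = c(1409,  986,  67, 1258,  4905, 1317,  3530,  215)
  )
  dimnames(m) <- list(stage_levels(), group_levels())
  storage.mode(m) <- "integer"
  m
}

#' Balanced per-group epoch targets
#'
#' The per-class target used for each group after over-/under-sampling
#' (every stage of a group gets the same count; balanced grand total 80,442),
#' plus the two combined subsets.
#'
#' @return named integer vector over [group_levels()] plus
#'   \code{"all_disordered"} and \code{"all_combined"}.
#' @export
cap_balanced_targets <- function() {
  c(healthy = 1000L, insomnia = 1400L, bruxism = 71L, narcolepsy = 935L,
    NFLE = 4480L, PLM = 1262L, RBD = 3779L, SDB = 480L,
    all_disordered = 12500L, all_combined = 14000L)
}

#' Trial accuracies of the healthy subset (combined channels)
#'
#' The five repeated 10-fold CV trial accuracies reported for the healthy,
#' unbalanced, dual-channel configuration.
#'
#' @return numeric vector of five percentages.
#' @export
cap_healthy_trial_accuracies <- function() {
  c(76.26, 77.66, 79.06, 79.66, 78.86)
}

#' Published row-percent confusion tables
#'
#' Two reference confusion matrices in row-percent form with their true-class
#' row totals: \code{"healthy_unbalanced"} (6063 epochs) and
#' \code{"insomnia_balanced"} (1400 epochs per stage).
#'
#' @param which table name.
#' @return list with \code{pct} (6x6 row-percent matrix) and
#'   \code{row_totals}.
#' @export
cap_confusion_table <- function(which = c("healthy_unbalanced",
                                          "insomnia_balanced")) {
  which <- match.arg(which)
  if (which == "healthy_unbalanced") {
    pct <- rbind(
      W   = c(68.8, 15.7,  5.4,  0.9,  0.4,  8.8),
      S1  = c(21.4, 42.5, 23.2,  0.0,  0.7, 12.1),
      S2  = c( 1.3,  2.3, 80.9,  6.0,  1.2,  8.4),
      S3  = c( 0.9,  0.2, 28.6, 56.9, 12.6,  0.9),
      S4  = c( 0.3,  0.1,  1.9,  5.7, 91.7,  0.2),
      REM = c( 1.1,  1.8, 11.8,  0.9,  0.5, 84.0)
    )
    totals <- cap_epoch_counts()[, "healthy"]
  } else {
    pct <- rbind(
      W   = c(92.1,  4.0,  2.7,  0.2,  0.3,  0.6),
      S1  = c( 0.0, 100.0, 0.0,  0.0,  0.0,  0.0),
      S2  = c( 5.6,  4.5, 74.1,  7.1,  0.7,  7.9),
      S3  = c( 0.3,  0.0,  1.1, 97.1,  1.4,  0.0),
      S4  = c( 0.0,  0.0,  0.0,  0.0, 100.0, 0.0),
      REM = c( 1.1,  1.1,  3.9,  0.1,  0.1, 93.6)
    )
    totals <- stats::setNames(rep(1400L, 6L), stage_levels())
  }
  colnames(pct) <- stage_levels()
  list(pct = pct, row_totals = totals)
}

#' Synthetic cohort spec mirroring the CAP class imbalance
#'
#' Convenience wrapper building a [cohort_spec()] whose per-stage counts are
#' the published per-group counts, optionally scaled down for desk-scale
#' runs.
#'
#' @param groups subset of [group_levels()].
#' @param scale multiplier applied to the counts (rounded, minimum 1 epoch
#'   where the original count is positive).
#' @param fs,epoch_s,seed,channels passed to [cohort_spec()].
#' @return a \code{"cohort_spec"}.
#' @export
cap_cohort_spec <- function(groups = "healthy", scale = 1, fs = 512,
                            epoch_s = 30, seed = 1L,
                            channels = c("F4-C4", "C4-A1")) {
  counts <- cap_epoch_counts()[, groups, drop = FALSE]
  glist <- lapply(seq_along(groups), function(i) {
    cnt <- counts[, i]
    scaled <- ifelse(cnt > 0, pmax(1L, as.integer(round(cnt * scale))), 0L)
    stats::setNames(scaled, rownames(counts))
  })
  names(glist) <- groups
  cohort_spec(glist, fs = fs, epoch_s = epoch_s, seed = seed,
              channels = channels)
}
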