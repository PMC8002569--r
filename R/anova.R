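# Feature screening: one-way ANOVA per feature across the six stages,
# ranking by the F statistic, and unprotected Fisher LSD post-hoc pairwise
# comparisons at 95% confidence.

#' One-way ANOVA for a single feature
#'
#' Standard between/within mean-square ratio via [stats::lm()]/
#' [stats::anova()], with the p-value from the F distribution on
#' \eqn{(g - 1, N - g)} degrees of freedom.
#'
#' @param values numeric per-sample feature values.
#' @param groups class labels.
#' @return list with \code{F}, \code{p}, \code{df} and the fitted mean
#'   squares.
#' @export
anova_oneway <- function(values, groups) {
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(g) < 2L)) {
    stop("every group needs at least two samples", call. = FALSE)
  }
  fit <- stats::lm(values ~ g)
  a <- stats::anova(fit)
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1],
       df = c(between = a$Df[1], within = a$Df[2]),
       ms_between = a$`Mean Sq`[1], ms_within = a$`Mean Sq`[2])
}

#' Rank features by class separation
#'
#' One-way ANOVA of every feature against the stage labels; features ranked
#' by descending F statistic (1 = most separating).  Per-class mean and
#' (sample) standard deviation accompany each feature, mirroring the
#' published screening tables.
#'
#' @param m a \code{"feature_matrix"}.
#' @return data.frame of class \code{"anova_result"}: one row per feature
#'   with \code{F}, \code{p}, \code{rank} and per-class \code{mean}/\code{sd}
#'   columns.
#' @export
rank_features <- function(m) {
  fn <- feature_names(m)
  y <- stage_factor(m$label)
  rows <- lapply(fn, function(f) {
    v <- m[[f]]
    a <- anova_oneway(v, y)
    stats_by <- vapply(stage_levels(), function(s) {
      c(mean(v[y == s]), stats::sd(v[y == s]))
    }, numeric(2))
    row <- data.frame(feature = f, F = a$F, p = a$p)
    for (s in stage_levels()) {
      row[[paste0(s, "_mean")]] <- stats_by[1, s]
      row[[paste0(s, "_sd")]] <- stats_by[2, s]
    }
    row
  })
  out <- do.call(rbind, rows)
  out$rank <- as.integer(rank(-out$F, ties.method = "first"))
  out <- out[, c("feature", "rank", "F", "p",
                 as.vector(t(outer(stage_levels(), c("_mean", "_sd"), paste0))))]
  structure(out[order(out$rank), ], class = c("anova_result", "data.frame"))
}

#' Fisher least-significant-difference post-hoc test
#'
#' For each pair of groups, compares \eqn{|\bar x_i - \bar x_j|} against
#' \eqn{t_{1-\alpha/2, N-g} \sqrt{MSE (1/n_i + 1/n_j)}} using the pooled
#' within-group mean square from the one-way ANOVA.  LSD is unprotected by
#' definition: the pairwise table is computed regardless of the overall
#' ANOVA outcome, with a flag when the overall test does not reject.
#'
#' @param values numeric per-sample feature values.
#' @param groups class labels.
#' @param alpha significance level (default 0.05, i.e. 95% confidence).
#' @return data.frame with one row per unordered pair: group means, mean
#'   difference, the LSD threshold and \code{significant}; the overall ANOVA
#'   p-value and an \code{anova_rejects} flag are attached as attributes.
#' @export
fisher_lsd <- function(values, groups, alpha = 0.05) {
  g <- droplevels(as.factor(groups))
  a <- anova_oneway(values, g)
  n <- table(g)
  means <- tapply(values, g, mean)
  lv <- levels(g)
  tcrit <- stats::qt(1 - alpha / 2, df = a$df[["within"]])
  pairs <- utils::combn(lv, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(kk) {
    i <- pairs[1, kk]; j <- pairs[2, kk]
    lsd <- tcrit * sqrt(a$ms_within * (1 / n[[i]] + 1 / n[[j]]))
    d <- means[[i]] - means[[j]]
    data.frame(group_i = i, group_j = j,
               mean_i = means[[i]], mean_j = means[[j]],
               difference = d, lsd = lsd,
               significant = abs(d) > lsd,
               stringsAsFactors = FALSE)
  }))
  if (a$p > alpha) {
    message(sprintf(
      "fisher_lsd: overall ANOVA does not reject (p = %.3g); unprotected pairwise results flagged",
      a$p))
  }
  structure(out, anova_p = a$p, anova_rejects = a$p <= alpha)
}
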