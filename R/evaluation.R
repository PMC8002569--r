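# Evaluation protocol: repeated stratified 10-fold cross-validation with
# confusion matrices (counts and row-percent views), overall and per-class
# one-vs-rest accuracy, F1, Cohen's kappa with its across-trial error, and
# one-vs-rest ROC/AUC.  Trial aggregation uses the population (divide-by-n)
# standard deviation.

#' Population standard deviation
#'
#' Divide-by-n standard deviation, the convention used to aggregate the five
#' cross-validation trials (e.g. trial accuracies 76.26, 77.66, 79.06, 79.66,
#' 78.86 give 78.3 +/- 1.21).
#'
#' @param x numeric vector.
#' @return scalar.
#' @export
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

#' Multiclass confusion matrix
#'
#' Rows are true classes, columns predicted, in the canonical class order.
#'
#' @param y_true,y_pred class labels (factors or characters over the same
#'   class set).
#' @param classes class order; defaults to [stage_levels()] when the labels
#'   are sleep stages.
#' @return integer matrix of class \code{"confusion_matrix"}.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  if (is.null(classes)) {
    classes <- if (is.factor(y_true)) levels(y_true)
               else if (all(unique(as.character(y_true)) %in% stage_levels()))
                 stage_levels()
               else sort(unique(as.character(y_true)))
  }
  cm <- table(factor(as.character(y_true), levels = classes),
              factor(as.character(y_pred), levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Row-percent view of a confusion matrix
#'
#' Each row divided by its row sum, times 100 (the layout of the published
#' confusion-matrix tables).
#'
#' @param cm a confusion matrix (counts).
#' @return numeric matrix of percentages.
#' @export
row_percent <- function(cm) {
  rs <- rowSums(cm)
  rs[rs == 0] <- 1
  100 * sweep(unclass(cm), 1, rs, "/")
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm counts matrix.
#' @return percent, \code{100 * trace / total}.
#' @export
overall_accuracy <- function(cm) {
  100 * sum(diag(unclass(cm))) / sum(cm)
}

#' Per-class one-vs-rest accuracy
#'
#' Collapses the matrix to \code{class} versus rest and returns
#' \code{100 * (TP + TN) / total}.  A class that never occurs and is never
#' predicted scores 100 (degenerate; a message is emitted).
#'
#' @param cm counts matrix.
#' @param class class name (row/column label).
#' @return percent.
#' @export
per_class_ovr_accuracy <- function(cm, class) {
  cm <- unclass(cm)
  i <- match(class, rownames(cm))
  if (is.na(i)) stop(sprintf("unknown class '%s'", class), call. = FALSE)
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  if (tp + fn + fp == 0) {
    message(sprintf("class '%s' absent and never predicted; one-vs-rest accuracy is degenerate", class))
  }
  100 * (tp + tn) / sum(cm)
}

#' Per-class F1 score
#'
#' \eqn{F_1 = 2PR/(P+R)} with precision \eqn{P = TP/(TP+FP)} and recall
#' \eqn{R = TP/(TP+FN)}; 0 when \eqn{P + R = 0}.
#'
#' @param cm counts matrix.
#' @param class class name.
#' @return value in \code{[0, 1]}.
#' @export
f1_per_class <- function(cm, class) {
  cm <- unclass(cm)
  i <- match(class, rownames(cm))
  if (is.na(i)) stop(sprintf("unknown class '%s'", class), call. = FALSE)
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' \eqn{p_e = \sum_i r_i c_i / N^2} from the row and column marginals.  With
#' exactly uniform true-class counts \eqn{p_e = 1/6} for six classes.
#'
#' @param cm counts matrix.
#' @return \eqn{\kappa} in \code{[-1, 1]}.
#' @export
cohens_kappa <- function(cm) {
  cm <- unclass(cm)
  N <- sum(cm)
  po <- sum(diag(cm)) / N
  pe <- sum(rowSums(cm) * colSums(cm)) / N^2
  if (pe >= 1) return(ifelse(po >= 1, 1, 0))
  (po - pe) / (1 - pe)
}

#' Rebuild confusion-matrix counts from a row-percent table
#'
#' Inverse of [row_percent()] given the true-class row totals, used to
#' reconstruct published row-percent confusion tables for metric arithmetic.
#' Counts are rounded to the nearest integer.
#'
#' @param pct numeric 6x6 row-percent matrix.
#' @param row_totals true-class counts, one per row.
#' @param classes class labels.
#' @return a \code{"confusion_matrix"}.
#' @export
cm_from_row_percent <- function(pct, row_totals, classes = stage_levels()) {
  pct <- as.matrix(pct)
  stopifnot(nrow(pct) == length(row_totals))
  counts <- round(sweep(pct / 100, 1, row_totals, "*"))
  m <- matrix(as.integer(counts), nrow = nrow(pct),
              dimnames = list(true = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, digits = 1, ...) {
  cat("Confusion matrix (counts):\n")
  print(unclass(x))
  cat("\nRow-percent view:\n")
  print(round(row_percent(x), digits))
  cat(sprintf("\nOverall accuracy = %.1f%%, Cohen's kappa = %.4f\n",
              overall_accuracy(x), cohens_kappa(x)))
  invisible(x)
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so per-fold class proportions stay within one sample of global
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.factor(y)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (!length(idx)) next
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Repeated stratified k-fold cross-validation of the bagged ensemble
#'
#' Per trial: a fresh stratified k-fold split; each fold is held out once,
#' the ensemble trained on the rest; trial accuracy is the mean of the fold
#' accuracies and trial kappa comes from the trial's pooled confusion
#' matrix.  Across trials the mean and population standard deviation are
#' reported for both, together with the all-trials pooled confusion matrix,
#' per-class one-vs-rest accuracy, F1 and one-vs-rest AUC.
#'
#' @param X feature matrix (or \code{"feature_matrix"}).
#' @param y class labels.
#' @param n_learners,max_splits ensemble configuration ([fit_bagged()]).
#' @param k folds (10 in the study protocol).
#' @param trials repetitions of the k-fold split (5 in the protocol).
#' @param seed master seed; folds and bootstraps derive from it.
#' @return object of class \code{"cv_result"}.
#' @export
repeated_cv <- function(X, y, n_learners = 30L, max_splits = NULL,
                        k = 10L, trials = 5L, seed = 1L) {
  Xm <- as_design_matrix(X)
  y <- as_class_factor(y)
  present <- table(y)
  low <- names(present)[present > 0 & present < k]
  if (length(low)) {
    stop(sprintf(
      "class(es) %s have fewer than k = %d members; reduce k or rebalance the data",
      paste(low, collapse = ", "), k), call. = FALSE)
  }
  classes <- levels(y)
  per_trial_accuracy <- numeric(trials)
  per_trial_kappa <- numeric(trials)
  pooled <- matrix(0L, length(classes), length(classes),
                   dimnames = list(true = classes, predicted = classes))
  scores <- matrix(NA_real_, length(y), length(classes),
                   dimnames = list(NULL, classes))
  for (tr in seq_len(trials)) {
    folds <- stratified_folds(y, k, seed = derive_seed(seed, "folds", tr))
    fold_acc <- numeric(k)
    trial_cm <- pooled * 0L
    for (fi in seq_len(k)) {
      test <- folds == fi
      fit <- fit_bagged(Xm[!test, , drop = FALSE], y[!test],
                        n_learners = n_learners, max_splits = max_splits,
                        seed = derive_seed(seed, "bag", tr, fi))
      prob <- predict(fit, Xm[test, , drop = FALSE], type = "prob")
      pred <- factor(classes[max.col(prob, ties.method = "first")],
                     levels = classes)
      fold_acc[fi] <- 100 * mean(pred == y[test])
      trial_cm <- trial_cm + unclass(confusion_matrix(y[test], pred, classes))
      if (tr == trials) scores[test, ] <- prob   # last trial's OOF scores
    }
    per_trial_accuracy[tr] <- mean(fold_acc)
    per_trial_kappa[tr] <- cohens_kappa(trial_cm)
    pooled <- pooled + trial_cm
  }
  cmat <- structure(pooled, class = c("confusion_matrix", "matrix"))
  per_class <- data.frame(
    class = classes,
    ovr_accuracy = vapply(classes, function(cl) per_class_ovr_accuracy(cmat, cl), 1),
    f1 = vapply(classes, function(cl) f1_per_class(cmat, cl), 1),
    auc = vapply(classes, function(cl) {
      if (!sum(y == cl)) return(NA_real_)
      roc_ovr(scores, y, classes = classes)[[cl]]$auc
    }, 1),
    row.names = NULL
  )
  structure(list(
    per_trial_accuracy = per_trial_accuracy,
    mean_accuracy = mean(per_trial_accuracy),
    std_accuracy = pop_sd(per_trial_accuracy),
    per_trial_kappa = per_trial_kappa,
    kappa_mean = mean(per_trial_kappa),
    kappa_error = pop_sd(per_trial_kappa),
    confusion = cmat,
    per_class = per_class,
    scores = scores,
    k = k, trials = trials, seed = seed,
    n_learners = n_learners, max_splits = max_splits
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Repeated %d-fold CV, %d trial(s):\n", x$k, x$trials))
  cat(sprintf("  accuracy = %.1f +/- %.2f %%\n", x$mean_accuracy, x$std_accuracy))
  cat(sprintf("  kappa    = %.4f +/- %.4f\n", x$kappa_mean, x$kappa_error))
  cat("  per-class (one-vs-rest):\n")
  print(transform(x$per_class,
                  ovr_accuracy = round(ovr_accuracy, 2),
                  f1 = round(f1, 3), auc = round(auc, 3)))
  invisible(x)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, its score column is swept over all thresholds (the class
#' against the remaining classes pooled); AUC by the trapezoid rule.
#'
#' @param scores numeric matrix of class scores, one column per class.
#' @param y_true true labels.
#' @param classes class order (defaults to the score column names).
#' @return named list; per class a list with \code{curve} (data.frame fpr,
#'   tpr) and \code{auc}.
#' @export
roc_ovr <- function(scores, y_true, classes = colnames(scores)) {
  scores <- as.matrix(scores)
  if (is.null(classes)) stop("scores must have class column names", call. = FALSE)
  y <- as.character(y_true)
  out <- lapply(classes, function(cl) {
    s <- scores[, cl]
    keep <- !is.na(s)
    s <- s[keep]; pos <- y[keep] == cl
    np <- sum(pos); nn <- sum(!pos)
    if (np == 0 || nn == 0) {
      return(list(curve = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                  auc = NA_real_))
    }
    ord <- order(s, decreasing = TRUE)
    tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
    # collapse tied scores to single operating points
    last_of_tie <- c(diff(s[ord]) != 0, TRUE)
    tpr <- c(0, tp[last_of_tie] / np)
    fpr <- c(0, fp[last_of_tie] / nn)
    auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
    list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
  })
  names(out) <- classes
  out
}
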