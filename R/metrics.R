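#' Binary confusion tallies
#'
#' @param predicted,truth 0/1 vectors of equal length.
#' @return object of class `confusion_counts` with fields TP, FN, TN, FP.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  if (!all(predicted %in% 0:1) || !all(truth %in% 0:1)) {
    stop("invalid input: confusion tallies need 0/1 vectors")
  }
  structure(list(
    TP = sum(predicted == 1 & truth == 1),
    FN = sum(predicted == 0 & truth == 1),
    TN = sum(predicted == 0 & truth == 0),
    FP = sum(predicted == 1 & truth == 0)
  ), class = "confusion_counts")
}

#' Screening statistics from confusion tallies
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / total`. A zero denominator is an error, never a
#' silent zero.
#'
#' @param counts a [confusion_counts()].
#' @return scalar in `[0, 1]`.
#' @export
sensitivity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  den <- counts$TP + counts$FN
  if (den == 0) stop("undefined statistic: no positive truth samples")
  counts$TP / den
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  den <- counts$TN + counts$FP
  if (den == 0) stop("undefined statistic: no negative truth samples")
  counts$TN / den
}

#' @rdname sensitivity
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TP + counts$FN + counts$TN + counts$FP
  if (total == 0) stop("undefined statistic: no samples")
  (counts$TP + counts$TN) / total
}

#' Wilson score confidence interval for a proportion
#'
#' @param x successes, `n` trials, `conf` confidence level.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return length-2 vector `c(lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) stop("undefined statistic: zero trials")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, center - half), min(1, center + half))
}

#' Binarize five-level grades into referable disease
#'
#' Referable disease is moderate or worse: grade >= 2 maps to 1, grades 0-1
#' map to 0.
#'
#' @param grades integer vector with values in 0..4.
#' @return integer 0/1 vector.
#' @export
referable_binarize <- function(grades) {
  g <- as.integer(grades)
  if (any(is.na(g)) || any(g < 0 | g > 4)) {
    stop("invalid input: grades must lie in 0..4")
  }
  as.integer(g >= 2)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (predicting positive
#' when `score >= threshold`), records the true- and false-positive rates,
#' and integrates the curve by the trapezoidal rule. Tied scores move along
#' the sweep together, so the area equals the Mann-Whitney pair-count
#' statistic (ties credited one half).
#'
#' @param scores numeric score per sample (larger = more positive-looking).
#' @param truth 0/1 truth vector with at least one of each class.
#' @return object of class `roc_curve`: list with `thresholds`, `tpr`,
#'   `fpr`, `auc`.
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  if (!all(truth %in% 0:1)) stop("invalid input: truth must be 0/1")
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("undefined statistic: ROC needs at least one positive and one negative")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- numeric(length(thr))
  fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pos <- scores >= thr[i]
    tpr[i] <- sum(pos & truth == 1) / n_pos
    fpr[i] <- sum(pos & truth == 0) / n_neg
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}
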