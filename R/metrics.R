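#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC for a binary outcome. Tied scores
#' contribute 1/2, so the value equals the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param scores Numeric vector of risk scores (higher = more likely positive).
#' @param labels Binary vector (0/1 or logical) of outcomes.
#' @return AUROC in \[0, 1\]; `NA` if either class is absent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average precision: AP = sum over score thresholds of
#' (recall step) x (precision at that threshold). Tied scores form a
#' single threshold, so the value is invariant to the ordering of ties.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\]; `NA` if no positives.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  npos <- sum(labels == 1L)
  if (npos == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  cum_tp <- cumsum(lab)
  n_at <- seq_along(lab)
  # thresholds = last index of each tied-score block
  last <- cumsum(rle(sc)$lengths)
  tp <- cum_tp[last]
  prec <- tp / n_at[last]
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' Classification accuracy at a probability threshold
#'
#' @inheritParams auroc
#' @param threshold Scores at or above this value are called positive.
#' @return Fraction of correct calls.
#' @export
accuracy <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  mean(as.integer(scores >= threshold) == labels)
}
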