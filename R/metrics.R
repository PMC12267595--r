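# Threshold bookkeeping and the standard binary-classification metrics:
# sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
# accuracy = (TP+TN)/(TP+TN+FP+FN) (reported on the 0-100 scale),
# MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
# AUC = rank-based (Mann-Whitney) probability that a random positive
# outscores a random negative, ties counted one half.

asBinaryLabels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    stopifnot(all(labels %in% c("positive", "negative")))
    labels <- as.integer(labels == "positive")
  }
  stopifnot(all(labels %in% c(0, 1)))
  as.integer(labels)
}

#' Confusion counts at a probability threshold
#'
#' A score greater than or equal to `threshold` is a positive call (ties at
#' the threshold count as positive).
#'
#' @param scores numeric scores/probabilities, one per row.
#' @param labels class labels (`"positive"`/`"negative"`, or 1/0).
#' @param threshold decision threshold (default 0.5).
#' @return named list `TP`, `FP`, `TN`, `FN`.
#' @examples
#' confusionCounts(c(0.9, 0.1), c(1, 0))
#' @export
confusionCounts <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0) stop("empty input")
  y <- asBinaryLabels(labels)
  stopifnot(length(scores) == length(y))
  call_pos <- scores >= threshold
  list(TP = sum(call_pos & y == 1), FP = sum(call_pos & y == 0),
       TN = sum(!call_pos & y == 0), FN = sum(!call_pos & y == 1))
}

#' Rank-based ROC AUC
#'
#' @inheritParams confusionCounts
#' @return AUC in \[0, 1\]; `NA` when a class is absent.
#' @export
aucScore <- function(scores, labels) {
  y <- asBinaryLabels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Matthews correlation coefficient
#'
#' Returns 0 when any factor of the denominator is 0 (degenerate
#' confusion).
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN`.
#' @return MCC in \[-1, 1\].
#' @export
mccScore <- function(counts) {
  with(counts, {
    denom2 <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    if (denom2 == 0) return(0)
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom2)
  })
}

#' Performance metrics bundle
#'
#' Computes sensitivity, specificity (0-1), accuracy (0-100), MCC and —
#' when scores are supplied — rank-based AUC, plus total and incorrect hit
#' counts for bookkeeping.
#'
#' @param counts confusion counts (list `TP`,`FP`,`TN`,`FN`), or `NULL` to
#'   derive them from `scores`/`labels` at `threshold`.
#' @inheritParams confusionCounts
#' @return named list: `sensitivity`, `specificity`, `accuracy`, `mcc`,
#'   `auc`, `total`, `incorrect`.
#' @examples
#' classMetrics(list(TP = 2100, FP = 121, TN = 402, FN = 151))
#' @export
classMetrics <- function(counts = NULL, scores = NULL, labels = NULL,
                         threshold = 0.5) {
  if (is.null(counts)) {
    if (is.null(scores) || is.null(labels))
      stop("supply counts or scores+labels")
    counts <- confusionCounts(scores, labels, threshold)
  }
  total <- with(counts, TP + FP + TN + FN)
  if (total <= 0) stop("empty confusion")
  list(
    sensitivity = with(counts, if (TP + FN > 0) TP / (TP + FN) else NA_real_),
    specificity = with(counts, if (TN + FP > 0) TN / (TN + FP) else NA_real_),
    accuracy = with(counts, 100 * (TP + TN) / total),
    mcc = mccScore(counts),
    auc = if (!is.null(scores) && !is.null(labels))
      aucScore(scores, labels) else NA_real_,
    total = total,
    incorrect = with(counts, FP + FN)
  )
}

#' Metrics table row in the report column order
#'
#' @param metrics list from [classMetrics()]
#' @return one-row data.frame with columns Sens, Spec, ACC, AUC, MCC.
#' @export
metricsRow <- function(metrics) {
  data.frame(Sens = metrics$sensitivity, Spec = metrics$specificity,
             ACC = metrics$accuracy, AUC = metrics$auc, MCC = metrics$mcc)
}
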