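#' Tie-aware ROC area under the curve
#'
#' Computed from probability ranks as the normalized Mann-Whitney statistic,
#' so ties contribute 1/2: equal scores for every observation give exactly
#' 50%, a perfect ranking 100%.
#'
#' @param truth logical vector (or factor coerced via `== positive`) marking
#'   positives.
#' @param scores numeric scores or probabilities for the positive class.
#' @return AUC as a percentage in \[0, 100\].
#' @export
roc_auc <- function(truth, scores) {
  truth <- as.logical(truth)
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0)
    metric_error("ROC-AUC needs at least one positive and one negative truth")
  r <- rank(scores, ties.method = "average")
  100 * (sum(r[truth]) - np * (np + 1) / 2) / (np * nn)
}

#' Binary classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total` and tie-aware ROC-AUC, all as percentages.
#'
#' @param truth vector of true classes.
#' @param predicted vector of predicted classes.
#' @param prob numeric vector of predicted probabilities for the positive
#'   class (used for the AUC); `NULL` omits the AUC.
#' @param positive the positive class.
#' @return Named numeric vector `c(sensitivity, specificity, accuracy,
#'   roc_auc)` in percent.
#' @examples
#' truth <- rep(c("A", "B"), c(10, 10))
#' pred  <- rep(c("A", "B", "A", "B"), c(8, 2, 1, 9))
#' classification_metrics(truth, pred, positive = "A")  # sens 80, spec 90
#' @export
classification_metrics <- function(truth, predicted, prob = NULL, positive) {
  tpos <- truth == positive
  if (all(tpos) || !any(tpos))
    metric_error("metrics are undefined for single-class truth")
  ppos <- predicted == positive
  tp <- sum(tpos & ppos); fn <- sum(tpos & !ppos)
  tn <- sum(!tpos & !ppos); fp <- sum(!tpos & ppos)
  out <- c(sensitivity = 100 * tp / (tp + fn),
           specificity = 100 * tn / (tn + fp),
           accuracy = 100 * (tp + tn) / length(truth),
           roc_auc = if (is.null(prob)) NA_real_ else roc_auc(tpos, prob))
  out
}

# One-vs-rest metrics for every class, given a probability matrix with one
# column per class.
multiclass_metrics <- function(truth, predicted, prob) {
  cls <- colnames(prob)
  out <- lapply(cls, function(cl)
    classification_metrics(truth, predicted, prob[, cl], positive = cl))
  names(out) <- cls
  do.call(rbind, out)
}
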