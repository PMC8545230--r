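#' Confusion counts for a binary classifier
#'
#' @param TP,TN,FP,FN Non-negative integer counts; at least one must be
#'   positive.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers", call. = FALSE)
  if (sum(v) == 0) stop("at least one count must be positive", call. = FALSE)
  structure(as.list(v), class = "confusion_counts")
}

#' Confusion counts from predicted and true labels
#'
#' @param truth,pred Label vectors of equal length.
#' @param positive The label treated as positive.
#' @return A `confusion_counts`.
#' @export
confusion_from_predictions <- function(truth, pred, positive) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  confusion_counts(TP = sum(pred == positive & truth == positive),
                   TN = sum(pred != positive & truth != positive),
                   FP = sum(pred == positive & truth != positive),
                   FN = sum(pred != positive & truth == positive))
}

#' Standard classification metrics from confusion counts
#'
#' Accuracy, precision, recall (sensitivity), specificity and F-score with
#' the conventional definitions. A ratio with zero denominator (e.g.
#' precision with no positive predictions) is reported as `NA` — an explicit
#' null marker, never a propagating `NaN`.
#'
#' @param c A [confusion_counts()].
#' @return List with `accuracy`, `precision`, `recall`, `specificity`,
#'   `f_score`.
#' @export
classification_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$TP + c$TN + c$FP + c$FN
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(c$TP, c$TP + c$FP)
  recall <- safe_div(c$TP, c$TP + c$FN)
  f_score <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(accuracy = safe_div(c$TP + c$TN, total),
       precision = precision,
       recall = recall,
       specificity = safe_div(c$TN, c$TN + c$FP),
       f_score = f_score)
}

#' Area under the ROC curve from scores
#'
#' Rank-based AUC: the probability that a random positive scores above a
#' random negative, computed with midranks (equivalently the normalized
#' Mann-Whitney U statistic).
#'
#' @param scores Numeric scores, higher meaning more positive.
#' @param labels Logical or 0/1 vector: `TRUE`/1 = positive.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("need both positive and negative labels", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
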