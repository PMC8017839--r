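#' Confusion counts for binary predictions
#'
#' @param labels True 0/1 labels.
#' @param predicted Predicted 0/1 labels (same length).
#' @return Named integer vector `c(tp, tn, fp, fn)`.
#' @export
confusion_counts <- function(labels, predicted) {
  if (length(labels) == 0L) stop("empty input", call. = FALSE)
  if (length(labels) != length(predicted)) stop("length mismatch", call. = FALSE)
  labels <- as.integer(labels); predicted <- as.integer(predicted)
  c(tp = sum(labels == 1L & predicted == 1L),
    tn = sum(labels == 0L & predicted == 0L),
    fp = sum(labels == 0L & predicted == 1L),
    fn = sum(labels == 1L & predicted == 0L))
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy, precision, recall, F1 and the false positive rate from
#' a confusion table. Ratios with a zero denominator (e.g. precision when
#' nothing is predicted positive) are returned as `NaN` rather than raising,
#' so cross-validation aggregates can skip them with a warning.
#'
#' The default F1 is the usual harmonic mean of precision and recall. Setting
#' `f1 = "printed"` substitutes accuracy for precision in the F1 formula — a
#' documented variant replicating a formula sometimes printed in the applied
#' literature.
#'
#' @param counts Output of [confusion_counts()], or `NULL` to compute it from
#'   `labels`/`predicted`.
#' @param labels,predicted Binary vectors, used when `counts` is `NULL`.
#' @param f1 `"standard"` or `"printed"`.
#' @return Named numeric vector: accuracy, precision, recall, f1, fpr.
#' @examples
#' classification_metrics(counts = c(tp = 3, tn = 2, fp = 1, fn = 0))
#' @export
classification_metrics <- function(counts = NULL, labels = NULL,
                                   predicted = NULL,
                                   f1 = c("standard", "printed")) {
  f1 <- match.arg(f1)
  if (is.null(counts)) counts <- confusion_counts(labels, predicted)
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  ratio <- function(num, den) if (is.nan(den) || den == 0) NaN else num / den
  acc <- ratio(tp + tn, tp + tn + fp + fn)
  prec <- ratio(tp, tp + fp)
  rec <- ratio(tp, tp + fn)
  f1_base <- if (f1 == "standard") prec else acc
  f1v <- ratio(2 * f1_base * rec, f1_base + rec)
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1v,
    fpr = ratio(fp, fp + tn))
}

#' ROC curve and area under the curve
#'
#' Sweeps every unique score as a threshold (ties grouped), accumulating the
#' true and false positive rates, and integrates the curve by the trapezoid
#' rule. The AUC equals the probability that a random positive outscores a
#' random negative (pairwise concordance, ties counted half).
#'
#' @param labels Binary 0/1 labels; both classes must be present.
#' @param scores Numeric scores, higher = more positive.
#' @return Object of class `roc_curve`: `thresholds` (decreasing), `fpr`,
#'   `tpr` (each starting at 0 and ending at 1) and `auc`.
#' @export
roc_curve <- function(labels, scores) {
  labels <- as.integer(labels)
  if (!all(c(0L, 1L) %in% labels)) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # Group tied scores: take cumulative counts at the last index of each tie run.
  last <- which(!duplicated(s, fromLast = TRUE))
  ctp <- cumsum(y == 1L)[last]
  cfp <- cumsum(y == 0L)[last]
  structure(list(thresholds = s[last],
                 fpr = c(0, cfp / N),
                 tpr = c(0, ctp / P),
                 auc = trapezoid_area(c(0, cfp / N), c(0, ctp / P))),
            class = "roc_curve")
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate", xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 3, col = "grey50")
  legend("bottomright", sprintf("AUC = %.4f", x$auc), bty = "n")
  invisible(x)
}
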