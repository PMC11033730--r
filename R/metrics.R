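## The five-metric evaluation suite for binary classifiers: ROC AUC
## (pairwise concordance, ties half-credit), area under the
## precision-recall curve (step summation, non-interpolated), and
## thresholded accuracy, Cohen's kappa and Matthews correlation.

#' Binary classification metric report
#'
#' Computes AUC, AUPR, accuracy, Cohen's kappa and the Matthews
#' correlation coefficient for a set of scores against 0/1 labels.
#'
#' AUC is the probability that a random positive outscores a random
#' negative, with ties counted half.  AUPR is the step-wise
#' (non-interpolated) sum `sum_k (R_k - R_{k-1}) P_k` over descending
#' score thresholds.  Accuracy, kappa and MCC come from the confusion
#' matrix at `threshold` (predicted positive when `score >= threshold`);
#' MCC is defined as 0 when any marginal factor is 0, and
#' `kappa = (p_o - p_e) / (1 - p_e)`.
#'
#' @param labels Named 0/1 vector.
#' @param scores Named numeric vector over the same ids.
#' @param threshold Classification threshold (default 0.5).
#' @return A `metric_report` list: `auc`, `aupr`, `accuracy`, `kappa`,
#'   `mcc`, `n_pos`, `n_neg`, `threshold`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  if (!is.null(names(labels)) && !is.null(names(scores))) {
    if (!setequal(names(labels), names(scores)))
      .stopf("label and score ids differ")
    scores <- scores[names(labels)]
  } else if (length(labels) != length(scores)) {
    .stopf("labels and scores lengths differ")
  }
  y <- as.integer(labels)
  if (any(is.na(scores)) || any(is.na(y))) .stopf("NA in labels or scores")
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0 || nn == 0) .stopf("undefined metric: both classes must be present")
  ## AUC via mid-ranks (equivalent to pairwise concordance with half ties)
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
  ## AUPR: descending unique thresholds, step summation
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp_end <- cumsum(rle(ss)$lengths)        # last index of each tied block
  tp <- cumsum(ys)[grp_end]
  npred <- grp_end
  prec <- tp / npred
  rec <- tp / np
  aupr <- sum(diff(c(0, rec)) * prec)
  ## confusion at threshold
  pred <- as.integer(scores >= threshold)
  TP <- as.numeric(sum(pred == 1 & y == 1)); FP <- as.numeric(sum(pred == 1 & y == 0))
  TN <- as.numeric(sum(pred == 0 & y == 0)); FN <- as.numeric(sum(pred == 0 & y == 1))
  n <- np + nn
  accuracy <- (TP + TN) / n
  pe <- ((TP + FP) * np + (TN + FN) * nn) / n^2
  kappa <- if (pe == 1) 0 else (accuracy - pe) / (1 - pe)
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom == 0) 0 else (TP * TN - FP * FN) / sqrt(denom)
  structure(list(auc = auc, aupr = aupr, accuracy = accuracy,
                 kappa = kappa, mcc = mcc,
                 n_pos = np, n_neg = nn, threshold = threshold),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("AUC %.3f | AUPR %.3f | acc %.3f | kappa %.3f | MCC %.3f  (%d pos / %d neg, thr %.2f)\n",
              x$auc, x$aupr, x$accuracy, x$kappa, x$mcc, x$n_pos, x$n_neg, x$threshold))
  invisible(x)
}
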