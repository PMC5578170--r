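#' Threshold classification metrics from confusion counts
#'
#' \deqn{ACC = (TP + TN) / (TP + FP + TN + FN)}
#' \deqn{SN = TP / (TP + FN)} (sensitivity / recall)
#' \deqn{Spec = TN / (TN + FP)}
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return list with `acc`, `sn`, `spec` and the counts.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  list(acc = (tp + tn) / (tp + fp + tn + fn),
       sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

# order scores decreasing and accumulate counts; ties are grouped so curve
# points correspond to distinct thresholds
.curve_counts <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels > 0
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one positive and one negative label", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  last <- cumsum(rle(s)$lengths)       # last index of each distinct score
  list(tp = cumsum(p)[last], fp = cumsum(!p)[last],
       n_pos = n_pos, n_neg = n_neg)
}

#' ROC curve points
#'
#' @param scores real-valued decision scores (larger = more positive).
#' @param labels +1/-1 (or logical / 0-1) true labels.
#' @return data.frame with `fpr`, `tpr`, `threshold` (one row per distinct
#'   score, plus the (0,0) origin).
#' @export
roc_points <- function(scores, labels) {
  cc <- .curve_counts(scores, labels)
  data.frame(fpr = c(0, cc$fp / cc$n_neg), tpr = c(0, cc$tp / cc$n_pos),
             threshold = c(Inf, sort(unique(scores), decreasing = TRUE)))
}

#' Area under the ROC curve (trapezoidal)
#'
#' Trapezoidal integration of the ROC curve; with tied scores this equals
#' the Mann-Whitney statistic with the usual 1/2 credit for ties.
#'
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  r <- roc_points(scores, labels)
  sum(diff(r$fpr) * (head(r$tpr, -1L) + r$tpr[-1L]) / 2)
}

#' Precision-recall curve points
#'
#' @inheritParams roc_points
#' @return data.frame with `recall`, `precision`, `threshold`.
#' @export
pr_points <- function(scores, labels) {
  cc <- .curve_counts(scores, labels)
  data.frame(recall = cc$tp / cc$n_pos,
             precision = cc$tp / (cc$tp + cc$fp),
             threshold = sort(unique(scores), decreasing = TRUE))
}

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision style) integration:
#' \eqn{\sum_i (R_i - R_{i-1}) P_i} over the curve points, with no linear
#' interpolation between points — interpolating precision linearly is known
#' to overstate AUPR.
#'
#' @inheritParams roc_points
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(scores, labels) {
  pr <- pr_points(scores, labels)
  sum(diff(c(0, pr$recall)) * pr$precision)
}

#' Per-fold evaluation of decision scores
#'
#' Thresholds scores at `cutoff` for the confusion-based metrics and
#' integrates the full curves for AUC/AUPR.
#'
#' @param scores decision values for one test fold.
#' @param labels true +1/-1 labels.
#' @param cutoff decision threshold (default 0).
#' @return one-row data.frame: `acc`, `sn`, `spec`, `auc`, `aupr`, `tp`,
#'   `fp`, `tn`, `fn`, `n`.
#' @export
score_fold <- function(scores, labels, cutoff = 0) {
  pred_pos <- scores > cutoff
  pos <- labels > 0
  cm <- confusion_metrics(tp = sum(pred_pos & pos), fp = sum(pred_pos & !pos),
                          tn = sum(!pred_pos & !pos), fn = sum(!pred_pos & pos))
  data.frame(acc = cm$acc, sn = cm$sn, spec = cm$spec,
             auc = auc_roc(scores, labels), aupr = aupr(scores, labels),
             tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
             n = length(labels))
}
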