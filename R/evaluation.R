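# Confusion-matrix metrics and ROC/AUC for segmentation and A/V
# classification results.

#' Confusion matrix from prediction and truth rasters
#'
#' For binary masks the positive class is 1.  For integer A/V label maps
#' the positive class defaults to artery; undefined pixels (and, for label
#' maps, background pixels) are excluded from the counts.
#'
#' @param pred predicted mask (0/1 matrix) or A/V label matrix (codes 0-3).
#' @param truth ground truth of the same type and shape.
#' @param positive for label maps: `"artery"` (default) or `"vein"`.
#' @return list with integer `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_from_masks <- function(pred, truth, positive = "artery") {
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth must share dimensions")
  is_labelmap <- any(truth == AV_VEIN | truth == AV_UNDEFINED) ||
    any(pred == AV_VEIN | pred == AV_UNDEFINED)
  if (is_labelmap) {
    pos_code <- if (positive == "artery") AV_ARTERY else AV_VEIN
    neg_code <- if (positive == "artery") AV_VEIN else AV_ARTERY
    keep <- truth %in% c(pos_code, neg_code) & pred %in% c(pos_code, neg_code)
    p <- pred[keep] == pos_code
    t <- truth[keep] == pos_code
  } else {
    p <- pred == 1
    t <- truth == 1
  }
  list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t),
       tn = sum(!p & !t))
}

metric_or_na <- function(num, den) if (den > 0) num / den else NA_real_

#' Classification metrics from a confusion matrix
#'
#' Accuracy, sensitivity (recall), specificity, precision, F1 and the
#' Matthews correlation coefficient.  Metrics with a zero denominator are
#' reported as `NA` with a warning, never silently as 0.
#'
#' @param cm list with `tp`, `fp`, `fn`, `tn`.
#' @return list of the six metrics (fractions in `[0, 1]`, MCC in
#'   `[-1, 1]`).
#' @export
compute_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  if (any(c(tp, fp, fn, tn) < 0)) stop("confusion counts must be >= 0")
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix")
  acc <- (tp + tn) / total
  sens <- metric_or_na(tp, tp + fn)
  spec <- metric_or_na(tn, tn + fp)
  prec <- metric_or_na(tp, tp + fp)
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  out <- list(accuracy = acc, sensitivity = sens, specificity = spec,
              precision = prec, f1 = f1, mcc = mcc)
  if (anyNA(unlist(out)))
    warning("one or more metrics undefined (zero denominator); reported as NA")
  out
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps every unique score as a threshold (predict positive when
#' `score >= t`) and integrates TPR over FPR with the trapezoidal rule.
#'
#' @param scores numeric vector of predicted probabilities.
#' @param truth 0/1 vector of the same length; both classes must be
#'   present.
#' @return list with `curve` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, truth) {
  scores <- as.vector(scores); truth <- as.vector(truth)
  if (length(scores) != length(truth)) stop("length mismatch")
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  # cumulative counts at each distinct threshold
  tps <- cumsum(t == 1); fps <- cumsum(t == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  thr <- s[keep]
  tpr <- c(0, tps[keep] / npos)
  fpr <- c(0, fps[keep] / nneg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr,
                          threshold = c(Inf, thr)),
       auc = auc)
}
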