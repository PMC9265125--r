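# ROC/AUC by the trapezoidal rule over all score thresholds. Tied scores
# collapse onto one ROC point, so the trapezoid handles ties the standard
# way (equivalent to the rank/Mann-Whitney statistic with 0.5 per tie).

#' ROC curve of a score vector
#'
#' @param scores numeric scores, larger = more class-1-like.
#' @param labels binary labels (0/1).
#' @return data frame with `threshold`, `fpr`, `tpr` (including the (0,0)
#'   and (1,1) endpoints).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) stop("ROC needs both classes")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  tp <- cumsum(l == 1)
  fp <- cumsum(l == 0)
  last <- !duplicated(s, fromLast = TRUE)  # one point per distinct threshold
  data.frame(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / sum(l == 0)),
    tpr = c(0, tp[last] / sum(l == 1))
  )
}

#' Area under the ROC curve (trapezoidal rule)
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
}
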