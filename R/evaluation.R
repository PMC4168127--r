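#' Confusion counts at a score threshold
#'
#' Prediction rule: `score >= t` predicts the minority (`+1`) class. The
#' boundary is inclusive; this orientation matters when scores tie with the
#' threshold and is fixed package-wide.
#'
#' @param scores numeric vector of minority-class confidences in `[0, 1]`.
#' @param labels vector over `{+1, -1}`.
#' @param t threshold.
#' @return named integer vector with elements `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(scores, labels, t) {
  if (length(scores) != length(labels)) abort_validation("scores/labels length mismatch")
  pred_pos <- scores >= t
  pos <- labels == 1
  c(tp = sum(pred_pos & pos), fp = sum(pred_pos & !pos),
    tn = sum(!pred_pos & !pos), fn = sum(!pred_pos & pos))
}

#' Threshold-dependent evaluation indexes
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/n`, and the Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' Any vanishing denominator yields 0 by convention, which keeps threshold
#' scans total over degenerate thresholds.
#'
#' @param counts confusion counts as returned by [confusion()].
#' @return named numeric vector `sen`, `spe`, `acc`, `mcc`.
#' @export
metrics <- function(counts) {
  tp <- as.numeric(counts[["tp"]]); fp <- as.numeric(counts[["fp"]])
  tn <- as.numeric(counts[["tn"]]); fn <- as.numeric(counts[["fn"]])
  n <- tp + fp + tn + fn
  if (n < 1) abort_validation("empty confusion counts")
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  c(sen = safe_div(tp, tp + fn),
    spe = safe_div(tn, tn + fp),
    acc = (tp + tn) / n,
    mcc = safe_div(tp * tn - fp * fn, den))
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formulation: the probability that a
#' uniformly chosen positive outscores a uniformly chosen negative, with ties
#' counted one half. Identical to the trapezoidal area under the ROC curve.
#'
#' @inheritParams confusion
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) abort_validation("scores/labels length mismatch")
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) abort_validation("AUC requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' One `(FPR, TPR)` point per candidate threshold, ordered by increasing FPR,
#' suitable for plotting or TSV export.
#'
#' @inheritParams confusion
#' @return data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  ts <- rev(candidate_thresholds(scores))
  pts <- t(vapply(ts, function(t) {
    cm <- confusion(scores, labels, t)
    m <- metrics(cm)
    c(fpr = 1 - m[["spe"]], tpr = m[["sen"]])
  }, numeric(2)))
  data.frame(threshold = ts, fpr = pts[, 1], tpr = pts[, 2])
}

#' Candidate thresholds: midpoints between adjacent distinct scores plus
#' sentinels below the minimum (everything positive) and above the maximum
#' (nothing positive).
#' @noRd
candidate_thresholds <- function(scores) {
  s <- sort(unique(scores))
  mids <- if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  c(s[1] - 1, mids, s[length(s)] + 1)
}

#' Select a decision threshold
#'
#' Scans the candidate thresholds (midpoints between adjacent distinct sorted
#' scores, plus sentinels) and applies the chosen policy:
#' \describe{
#'   \item{`max_mcc`}{the candidate maximising MCC; ties broken toward
#'     greater specificity, then the smaller threshold.}
#'   \item{`balanced`}{the candidate minimising `|Sen - Spe|`; ties broken
#'     toward greater MCC, then the smaller threshold.}
#'   \item{`fixed`}{evaluate at `fixed_value` without scanning.}
#' }
#'
#' @inheritParams confusion
#' @param policy `"max_mcc"`, `"balanced"` or `"fixed"`.
#' @param fixed_value threshold to use when `policy = "fixed"`.
#' @return list with `threshold`, `counts` and `metrics` at the selection.
#' @export
select_threshold <- function(scores, labels,
                             policy = c("max_mcc", "balanced", "fixed"),
                             fixed_value = NULL) {
  policy <- match.arg(policy)
  if (!any(labels == 1) || !any(labels == -1)) {
    abort_validation("threshold selection requires both classes present")
  }
  if (policy == "fixed") {
    if (is.null(fixed_value)) abort_validation("`fixed_value` required for policy 'fixed'")
    cm <- confusion(scores, labels, fixed_value)
    return(list(threshold = fixed_value, counts = cm, metrics = metrics(cm)))
  }
  cand <- candidate_thresholds(scores)
  tab <- t(vapply(cand, function(t) metrics(confusion(scores, labels, t)), numeric(4)))
  if (policy == "max_mcc") {
    ord <- order(-tab[, "mcc"], -tab[, "spe"], cand)
  } else {
    ord <- order(abs(tab[, "sen"] - tab[, "spe"]), -tab[, "mcc"], cand)
  }
  best <- ord[1]
  cm <- confusion(scores, labels, cand[best])
  list(threshold = cand[best], counts = cm, metrics = metrics(cm))
}

#' Full evaluation of scored predictions
#'
#' Threshold selection under a policy plus the threshold-free AUC.
#'
#' @inheritParams select_threshold
#' @return named numeric vector `threshold`, `sen`, `spe`, `acc`, `mcc`, `auc`.
#' @export
evaluate_predictions <- function(scores, labels, policy = "max_mcc",
                                 fixed_value = NULL) {
  sel <- select_threshold(scores, labels, policy, fixed_value)
  c(threshold = sel$threshold, sel$metrics, auc = roc_auc(scores, labels))
}
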