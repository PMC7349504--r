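#' ROC curve for a diagnostic index
#'
#' Builds the empirical ROC curve under the convention that a higher index
#' predicts disease: a patient is called positive when `score >= cutoff`.
#' Thresholds are the distinct observed score values (plus `Inf` for the
#' (0,0) corner); the AUC is the trapezoidal area. The orientation is never
#' flipped automatically — an AUC below 0.5 is reported as-is and flagged.
#'
#' @param scores Numeric index values (missing values dropped together with
#'   their labels).
#' @param labels Class labels; `positive` marks the diseased class.
#' @param positive Label of the diseased class (default `"MS"`).
#' @return Object of class `roc_curve`: data frame `points` with columns
#'   `threshold`, `fpr`, `tpr`, plus `auc`, `n_pos`, `n_neg`, and
#'   `uninformative` flag (`TRUE` when AUC < 0.5).
#' @export
#' @examples
#' roc_curve(c(2, 3, 0, 1), c("MS", "MS", "CONTROL", "CONTROL"))$auc  # 1
roc_curve <- function(scores, labels, positive = "MS") {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  pos <- labels[ok] == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC needs both classes present after dropping missing scores")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc, n_pos = n_pos, n_neg = n_neg,
                 uninformative = auc < 0.5),
            class = "roc_curve")
}

#' AUC by pairwise enumeration
#'
#' Mann-Whitney reading of the AUC: the fraction of (diseased, control)
#' pairs in which the diseased score is higher, counting ties as one half.
#' Serves as the independent route to the trapezoidal AUC of [roc_curve()];
#' the two agree to floating tolerance on every input.
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
auc_u_equivalence <- function(scores, labels, positive = "MS") {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  pos <- labels[ok] == positive
  sp <- scores[pos]; sn <- scores[!pos]
  if (!length(sp) || !length(sn))
    stop("AUC needs both classes present after dropping missing scores")
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

#' Optimal cut-off by Youden's J
#'
#' Selects, among the observed thresholds of a ROC curve, the one maximising
#' Youden's J = sensitivity + specificity - 1. Ties are broken in favour of
#' higher sensitivity, then of the lower threshold value (the screening
#' reading: never give up detection for the tie).
#'
#' @param curve A [roc_curve()] object.
#' @return List with `cutoff`, `j`, `sensitivity`, `specificity` (fractions),
#'   and `uninformative` flag (`TRUE` when max J = 0).
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  pts <- curve$points[is.finite(curve$points$threshold), ]
  j <- pts$tpr - pts$fpr
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[pts$tpr[best] == max(pts$tpr[best])]
  if (length(best) > 1L) best <- best[which.min(pts$threshold[best])]
  list(cutoff = pts$threshold[best], j = j[best],
       sensitivity = pts$tpr[best], specificity = 1 - pts$fpr[best],
       uninformative = max(j) <= 0)
}

#' Diagnostic performance at a cut-off
#'
#' Confusion counts and the five standard metrics under `score >= cutoff`
#' => positive. Metrics are percentages; a metric with a zero denominator is
#' `NA` and listed in `undefined` rather than propagating NaN. Unrounded
#' values are kept; `display` holds them rounded half-away-from-zero to
#' `decimals` places for table output.
#'
#' @inheritParams roc_curve
#' @param cutoff Decision threshold (inclusive).
#' @param decimals Display rounding (default 2).
#' @return Object of class `cutoff_performance`: `cutoff`, `confusion`
#'   (tp/fn/tn/fp), `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`
#'   (percent, unrounded), `auc`, `display`, `undefined`.
#' @export
#' @examples
#' performance_at_cutoff(c(10, 1, 8, 2), c("MS", "CONTROL", "MS", "CONTROL"), 5)
performance_at_cutoff <- function(scores, labels, cutoff, positive = "MS",
                                  decimals = 2L) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  pos <- labels[ok] == positive
  pred <- scores >= cutoff
  cm <- c(tp = sum(pred & pos), fn = sum(!pred & pos),
          tn = sum(!pred & !pos), fp = sum(pred & !pos))
  met <- .confusion_metrics(cm)
  auc <- if (any(pos) && any(!pos)) auc_u_equivalence(scores, ifelse(pos, "MS", "CONTROL")) else NA_real_
  structure(c(list(cutoff = cutoff, confusion = cm), as.list(met),
              list(auc = auc,
                   display = round_half_away(met, decimals),
                   undefined = names(met)[is.na(met)])),
            class = "cutoff_performance")
}

.confusion_metrics <- function(cm) {
  sdiv <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(sensitivity = sdiv(cm[["tp"]], cm[["tp"]] + cm[["fn"]]),
    specificity = sdiv(cm[["tn"]], cm[["tn"]] + cm[["fp"]]),
    ppv = sdiv(cm[["tp"]], cm[["tp"]] + cm[["fp"]]),
    npv = sdiv(cm[["tn"]], cm[["tn"]] + cm[["fn"]]),
    accuracy = sdiv(cm[["tp"]] + cm[["tn"]], sum(cm)))
}

#' @export
print.cutoff_performance <- function(x, ...) {
  cat(sprintf("cut-off >= %.4g  (tp %d, fn %d, tn %d, fp %d)\n", x$cutoff,
              x$confusion[["tp"]], x$confusion[["fn"]],
              x$confusion[["tn"]], x$confusion[["fp"]]))
  d <- x$display
  cat(sprintf("  sens %s  spec %s  ppv %s  npv %s  acc %s  auc %.3f\n",
              d[["sensitivity"]], d[["specificity"]], d[["ppv"]],
              d[["npv"]], d[["accuracy"]], x$auc))
  invisible(x)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: %d thresholds, %d pos / %d neg, AUC = %.4f%s\n",
              nrow(x$points), x$n_pos, x$n_neg, x$auc,
              if (x$uninformative) " [AUC < 0.5: check score orientation]" else ""))
  invisible(x)
}
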