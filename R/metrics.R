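#' Confusion counts of a binary classifier
#'
#' Tabulates predicted against actual labels (both in `{-1,+1}`) following the
#' standard convention: actual class in columns, predicted class in rows.
#'
#' @param y_true,y_pred equal-length label vectors in `{-1,+1}`.
#' @return An object of class `sfhe_confusion`: list with integer fields
#'   `tn`, `fn`, `fp`, `tp` summing to `length(y_true)`.
#' @examples
#' confusion(c(1, 1, -1, -1), c(1, -1, -1, 1))
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(y_true %in% c(-1, 1)) || !all(y_pred %in% c(-1, 1)))
    stop("labels must lie in {-1,+1}")
  structure(list(
    tn = sum(y_pred == -1 & y_true == -1),
    fn = sum(y_pred == -1 & y_true == 1),
    fp = sum(y_pred == 1 & y_true == -1),
    tp = sum(y_pred == 1 & y_true == 1)
  ), class = "sfhe_confusion")
}

#' @export
print.sfhe_confusion <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2,
              dimnames = list(predicted = c("-1", "+1"), actual = c("-1", "+1")))
  print(m)
  invisible(x)
}

#' True- and false-positive rates
#'
#' `TPR = TP / (TP + FN)` and `FPR = FP / (FP + TN)`. A zero denominator
#' (no actual positives, or no actual negatives) makes the corresponding rate
#' undefined and is signalled as an error rather than silently returned as 0.
#'
#' @param cm an [confusion()] object.
#' @return named numeric vector `c(TPR =, FPR =)`.
#' @export
rates <- function(cm) {
  stopifnot(inherits(cm, "sfhe_confusion"))
  if (cm$tp + cm$fn == 0L) stop("TPR undefined: no actual positives")
  if (cm$fp + cm$tn == 0L) stop("FPR undefined: no actual negatives")
  c(TPR = cm$tp / (cm$tp + cm$fn), FPR = cm$fp / (cm$fp + cm$tn))
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the classification threshold `tau` over the unique scores (ties
#' grouped at a single threshold) plus closure sentinels, predicting `+1` iff
#' `score >= tau`, and collects the `(FPR, TPR)` pairs. The curve therefore
#' starts at `(0, 0)` (threshold above every score) and ends at `(1, 1)`
#' (threshold at or below every score). The AUC is the trapezoidal area under
#' the sweep, which equals the Mann-Whitney U statistic divided by
#' `n_pos * n_neg` (ties counting 1/2).
#'
#' @param scores numeric classifier scores (higher means more positive);
#'   probabilities from [predict_proba()] in typical use.
#' @param y_true labels in `{-1,+1}`; at least one of each class.
#' @return An object of class `sfhe_roc`: list with `thresholds` (decreasing
#'   sweep), `points` (two-column matrix of FPR, TPR) and `auc`.
#' @export
roc_auc <- function(scores, y_true) {
  if (length(scores) != length(y_true)) stop("length mismatch")
  if (!all(y_true %in% c(-1, 1))) stop("labels must lie in {-1,+1}")
  npos <- sum(y_true == 1); nneg <- sum(y_true == -1)
  if (npos == 0L || nneg == 0L)
    stop("ROC undefined for single-class input")
  thr <- sort(unique(scores), decreasing = TRUE)
  thr <- c(Inf, thr)                        # closure: predict nothing positive
  ord <- order(scores, decreasing = TRUE)
  ys <- y_true[ord]
  ss <- scores[ord]
  # cumulative counts after including each tie group
  grp <- cumsum(!duplicated(ss))
  tp_cum <- cumsum(ys == 1)
  fp_cum <- cumsum(ys == -1)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp_cum[last] / npos)
  fpr <- c(0, fp_cum[last] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr,
                 points = cbind(FPR = fpr, TPR = tpr),
                 auc = auc),
            class = "sfhe_roc")
}

#' @export
print.sfhe_roc <- function(x, ...) {
  cat(sprintf("<sfhe_roc> %d sweep points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Export an ROC curve as a two-column CSV
#'
#' Writes the `(FPR, TPR)` sweep points for external plotting.
#'
#' @param roc an [roc_auc()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  stopifnot(inherits(roc, "sfhe_roc"))
  utils::write.csv(as.data.frame(roc$points), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
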