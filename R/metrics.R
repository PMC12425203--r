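# Evaluation metrics: accuracy, precision/recall/F1 with class-weighted (or
# macro) averaging, and binary ROC AUC by trapezoidal integration, with a
# pairwise-concordance formulation as an independent cross-check.

#' Binary classification metrics from confusion counts
#' @param TP,FP,FN,TN confusion counts
#' @return list with accuracy, precision, recall, f1
#' @export
binary_metrics_from_counts <- function(TP, FP, FN, TN) {
  total <- TP + FP + FN + TN
  prec <- if (TP + FP > 0) TP / (TP + FP) else 0
  rec <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(accuracy = (TP + TN) / total, precision = prec, recall = rec, f1 = f1)
}

#' Compute a metrics report
#'
#' Multiclass precision/recall/F1 are computed one-vs-rest per class and
#' averaged with class-support weights (`average = "weighted"`, the default)
#' or unweighted (`"macro"`). F1 is defined as 0 when precision + recall = 0.
#' AUC (binary truth only) uses trapezoidal ROC integration; see
#' [auc_trapezoid()] and [auc_concordance()].
#'
#' @param y_true,y_pred equal-length label vectors
#' @param scores optional scores for the positive class (binary AUC)
#' @param average `"weighted"` or `"macro"`
#' @return list of class `metrics_report`: accuracy, precision, recall, f1,
#'   auc (or NA), per_class data.frame with TP/FP/FN/TN and per-class
#'   metrics, n_samples
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL,
                            average = c("weighted", "macro")) {
  average <- match.arg(average)
  if (!length(y_true)) stop_invalid("empty input to compute_metrics")
  if (length(y_true) != length(y_pred)) stop_invalid("y_true/y_pred length mismatch")
  classes <- sort(unique(c(y_true, y_pred)))
  n <- length(y_true)
  per <- lapply(classes, function(cl) {
    TP <- sum(y_true == cl & y_pred == cl)
    FP <- sum(y_true != cl & y_pred == cl)
    FN <- sum(y_true == cl & y_pred != cl)
    TN <- n - TP - FP - FN
    m <- binary_metrics_from_counts(TP, FP, FN, TN)
    data.frame(class = cl, TP = TP, FP = FP, FN = FN, TN = TN,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               support = TP + FN)
  })
  per <- do.call(rbind, per)
  wts <- if (average == "weighted") per$support / sum(per$support) else
    rep(1 / nrow(per), nrow(per))
  auc <- NA_real_
  if (!is.null(scores)) {
    if (length(unique(y_true)) < 2L) {
      stop_invalid("AUC undefined: y_true contains a single class")
    }
    if (length(unique(y_true)) > 2L) {
      stop_invalid("AUC is computed for binary tasks only")
    }
    auc <- auc_trapezoid(scores, y_true == max(y_true))
  }
  structure(list(
    accuracy = mean(y_true == y_pred),
    precision = sum(wts * per$precision),
    recall = sum(wts * per$recall),
    f1 = sum(wts * per$f1),
    auc = auc,
    per_class = per,
    n_samples = n
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d acc=%.4f P=%.4f R=%.4f F1=%.4f%s\n",
              x$n_samples, x$accuracy, x$precision, x$recall, x$f1,
              if (is.na(x$auc)) "" else sprintf(" AUC=%.4f", x$auc)))
  invisible(x)
}

#' Binary ROC AUC by trapezoidal integration
#'
#' Builds the ROC curve over all distinct score thresholds (tied scores form
#' a single ROC segment) and integrates with the trapezoid rule, which
#' credits ties with 0.5 — numerically identical to [auc_concordance()].
#'
#' @param scores numeric scores, larger = more positive
#' @param labels logical/0-1 labels
#' @export
auc_trapezoid <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  P <- sum(y == 1L)
  N <- sum(y == 0L)
  if (P == 0L || N == 0L) stop_invalid("AUC undefined: single-class labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(yy, grp, sum)
  fp <- tapply(1L - yy, grp, sum)
  tpr <- c(0, cumsum(tp) / P)
  fpr <- c(0, cumsum(fp) / N)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Binary ROC AUC by pairwise concordance
#'
#' Fraction of (positive, negative) pairs where the positive scores higher;
#' tied pairs count 0.5. Independent formulation used as the oracle for
#' [auc_trapezoid()].
#'
#' @inheritParams auc_trapezoid
#' @export
auc_concordance <- function(scores, labels) {
  y <- as.logical(labels)
  sp <- scores[y]
  sn <- scores[!y]
  if (!length(sp) || !length(sn)) stop_invalid("AUC undefined: single-class labels")
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
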