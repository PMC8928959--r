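#' Confusion counts for a binary classification
#'
#' The positive class (label 1) is the antioxidant class.
#'
#' @param truth,predicted Equal-length binary (0/1) vectors.
#' @return An object of class `"confusion_counts"`: a named integer vector
#'   TP, FP, TN, FN.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  if (length(truth) < 1L) stop("empty label vectors", call. = FALSE)
  if (!all(truth %in% c(0L, 1L)) || !all(predicted %in% c(0L, 1L))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  structure(c(TP = sum(truth == 1L & predicted == 1L),
              FP = sum(truth == 0L & predicted == 1L),
              TN = sum(truth == 0L & predicted == 0L),
              FN = sum(truth == 1L & predicted == 0L)),
            class = "confusion_counts")
}

#' Imbalanced-classification statistics from confusion counts
#'
#' Computes sensitivity (recall), specificity, precision, accuracy, the
#' Matthews correlation coefficient (MCC), balanced accuracy
#' `(Sn + Sp) / 2`, Youden's index `Sn + Sp - 1`, the F1 score, and
#' Cohen's kappa via the observed agreement `Po` and the chance agreement
#' `Pe`. Any statistic whose denominator is zero (for example precision
#' with no predicted positives, or MCC with an empty margin) is reported
#' as `NA` rather than silently coerced to 0; aggregation across trials
#' ([aggregate_metrics()]) skips and counts these.
#'
#' @param counts A `"confusion_counts"` object, or anything coercible to a
#'   named numeric vector with entries TP, FP, TN, FN.
#' @return An object of class `"metric_report"`: a one-row data frame with
#'   columns `sensitivity`, `specificity`, `precision`, `accuracy`, `mcc`,
#'   `balanced_accuracy`, `youden`, `f1`, `po`, `pe`, `kappa`.
#' @examples
#' classification_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 0)))
#' @export
classification_metrics <- function(counts) {
  cc <- as.numeric(counts[c("TP", "FP", "TN", "FN")])
  if (anyNA(cc) || any(cc < 0)) stop("need nonnegative TP, FP, TN, FN", call. = FALSE)
  tp <- cc[1L]; fp <- cc[2L]; tn <- cc[3L]; fn <- cc[4L]
  n <- tp + fp + tn + fn
  if (n < 1) stop("empty confusion table", call. = FALSE)
  frac <- function(num, den) if (den > 0) num / den else NA_real_

  sn <- frac(tp, tp + fn)
  sp <- frac(tn, tn + fp)
  prec <- frac(tp, tp + fp)
  acc <- (tp + tn) / n
  mcc_den <- (tp + fp) * (tn + fn) * (tp + fn) * (tn + fp)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / sqrt(mcc_den) else NA_real_
  bacc <- if (!is.na(sn) && !is.na(sp)) (sn + sp) / 2 else NA_real_
  yi <- if (!is.na(sn) && !is.na(sp)) sn + sp - 1 else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sn) && (prec + sn) > 0) {
    2 * prec * sn / (prec + sn)
  } else NA_real_
  po <- acc
  pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_

  structure(data.frame(sensitivity = sn, specificity = sp, precision = prec,
                       accuracy = acc, mcc = mcc, balanced_accuracy = bacc,
                       youden = yi, f1 = f1, po = po, pe = pe, kappa = kappa),
            class = c("metric_report", "data.frame"))
}

#' Balanced accuracy and Youden's index from class recalls
#'
#' Convenience for recomputing the balanced statistics of a published
#' result table from its printed sensitivity and specificity columns.
#'
#' @param sensitivity,specificity Per-class recalls in `[0, 1]`
#'   (vectorized).
#' @return Data frame with columns `balanced_accuracy` and `youden`.
#' @export
balanced_stats <- function(sensitivity, specificity) {
  stopifnot(length(sensitivity) == length(specificity))
  data.frame(balanced_accuracy = (sensitivity + specificity) / 2,
             youden = sensitivity + specificity - 1)
}

#' Reconstruction error in decibels
#'
#' `-10 * log10(MSE)`; larger is better. For features on the unit range
#' (normalized CKSAAP compositions) this equals the peak signal-to-noise
#' ratio with peak 1. Identical matrices give `Inf`.
#'
#' @param original,decoded Equal-shaped numeric matrices.
#' @return Decibel value (possibly `Inf`).
#' @examples
#' mse_db(matrix(0, 2, 2), matrix(0.01, 2, 2))  # 40 dB
#' @export
mse_db <- function(original, decoded) {
  original <- as.matrix(original); decoded <- as.matrix(decoded)
  if (!identical(dim(original), dim(decoded))) {
    stop("matrices must have identical shapes", call. = FALSE)
  }
  mse <- mean((original - decoded)^2)
  if (mse == 0) Inf else -10 * log10(mse)
}

#' Areas under the ROC and precision-recall curves
#'
#' ROC-AUC is computed with \pkg{pROC}; PR-AUC by trapezoidal integration
#' of precision over recall at every score threshold.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param truth Binary 0/1 labels.
#' @return Numeric AUC value.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(unique(truth)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                 levels = c(0L, 1L), direction = "<")))
}

#' @rdname roc_auc
#' @export
pr_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  n_pos <- sum(truth == 1L)
  if (n_pos == 0L || n_pos == length(truth)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(truth[ord] == 1L)
  fp <- cumsum(truth[ord] == 0L)
  # one point per distinct threshold
  keep <- c(diff(scores[ord]) != 0, TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  recall <- c(0, tp / n_pos)
  precision <- c(1, tp / (tp + fp))
  sum(diff(recall) * (head(precision, -1L) + tail(precision, -1L)) / 2)
}

#' Aggregate metric reports across repeated trials
#'
#' @param reports A list of `"metric_report"` rows (or a data frame of
#'   them, one row per trial).
#' @return Data frame with one row per metric: `mean`, `sd`, `n_used`
#'   (trials with the metric defined) and `n_undefined` (skipped `NA`
#'   trials).
#' @export
aggregate_metrics <- function(reports) {
  df <- if (is.data.frame(reports)) reports else do.call(rbind, reports)
  num <- df[vapply(df, is.numeric, logical(1L))]
  out <- data.frame(
    metric = names(num),
    mean = vapply(num, function(v) mean(v[is.finite(v)]), numeric(1L)),
    sd = vapply(num, function(v) if (sum(is.finite(v)) > 1L) sd(v[is.finite(v)]) else 0,
                numeric(1L)),
    n_used = vapply(num, function(v) sum(is.finite(v)), integer(1L)),
    n_undefined = vapply(num, function(v) sum(!is.finite(v)), integer(1L)),
    row.names = NULL)
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion counts (positive = antioxidant):\n")
  print(unclass(x))
  invisible(x)
}

#' @export
print.metric_report <- function(x, ...) {
  vals <- vapply(unclass(x), function(v) {
    if (is.na(v)) "undefined" else formatC(v, digits = 3, format = "f")
  }, character(1L))
  cat(paste(sprintf("%-18s %s", names(vals), vals), collapse = "\n"), "\n")
  invisible(x)
}
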