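#' Confusion counts for binary interaction predictions
#'
#' Positives are interacting pairs (label 1), negatives non-interacting
#' (label 0): TP = interacting pairs predicted interacting, TN =
#' non-interacting predicted non-interacting, FP = non-interacting
#' predicted interacting, FN = interacting predicted non-interacting.
#'
#' @param truth Vector of true 0/1 labels.
#' @param estimate Vector of predicted 0/1 labels.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, estimate) {
  truth <- as.integer(as.character(truth))
  estimate <- as.integer(as.character(estimate))
  stopifnot(length(truth) == length(estimate),
            all(truth %in% 0:1), all(estimate %in% 0:1))
  tibble::tibble(
    tp = sum(truth == 1L & estimate == 1L),
    fp = sum(truth == 0L & estimate == 1L),
    tn = sum(truth == 0L & estimate == 0L),
    fn = sum(truth == 1L & estimate == 0L)
  )
}

#' Precision, sensitivity, accuracy and MCC from confusion counts
#'
#' \deqn{Pre = TP/(TP+FP), \quad Sen = TP/(TP+FN),}
#' \deqn{Acc = (TP+TN)/(TP+FP+TN+FN),}
#' \deqn{MCC = \frac{TP\cdot TN - FP\cdot FN}
#'   {\sqrt{(TP+FN)(TN+FP)(TP+FP)(TN+FN)}}.}
#'
#' A metric whose denominator is zero is reported as `NA` (undefined),
#' never coerced to 0, with a warning.
#'
#' @param counts One-row data frame with `tp`, `fp`, `tn`, `fn` (e.g. from
#'   [confusion_counts()]), or the four counts given separately.
#' @param tp,fp,tn,fn Counts, used when `counts` is missing.
#' @return One-row tibble with `pre`, `sen`, `acc`, `mcc` (proportions in
#'   \[0, 1\]; `mcc` in \[-1, 1\]).
#' @export
classification_metrics <- function(counts = NULL, tp = NULL, fp = NULL,
                                   tn = NULL, fn = NULL) {
  if (!is.null(counts)) {
    tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  }
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0) abort("all confusion counts are zero")
  div <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s is undefined (zero denominator); reporting NA", what))
      return(NA_real_)
    }
    num / den
  }
  mcc_den <- sqrt(prod(c(tp + fn, tn + fp, tp + fp, tn + fn)))
  tibble::tibble(
    pre = div(tp, tp + fp, "precision"),
    sen = div(tp, tp + fn, "sensitivity"),
    acc = (tp + tn) / total,
    mcc = div(tp * tn - fp * fn, mcc_den, "MCC")
  )
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the continuous scores (for DVM, the
#' residual difference `R_0 - R_1`) and integrates the ROC curve by the
#' trapezoidal rule. Tied scores receive the Mann-Whitney half-credit
#' convention, so the AUC equals the probability that a random positive
#' outscores a random negative (ties counting 1/2). A score set with no
#' class information gives AUC 0.5 (the diagonal). Computed with
#' \pkg{pROC}.
#'
#' @param scores Numeric scores, larger = more likely positive.
#' @param labels 0/1 labels (1 = positive/interacting).
#' @return List of class `roc_result`: `auc` (scalar) and `curve`, a
#'   tibble with `threshold`, `fpr`, `tpr` ordered along the sweep.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.character(labels))
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  if (length(unique(labels)) < 2L) {
    abort("ROC needs both classes present in `labels`")
  }
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  curve <- tibble::tibble(
    threshold = rev(r$thresholds),
    fpr = rev(1 - r$specificities),
    tpr = rev(r$sensitivities)
  )
  structure(list(auc = as.numeric(r$auc), curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d curve points)\n",
              x$auc, nrow(x$curve)))
  invisible(x)
}
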