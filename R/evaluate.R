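#' Evaluate continuous scores against binary truth
#'
#' Full ROC and precision–recall curves by threshold sweep (a sample is called
#' positive when its score is `>=` the threshold), trapezoidal AUCs, and an
#' operating point anchored on specificity: among thresholds whose specificity
#' is at least `spec_target`, the one closest to the target is chosen (ties
#' broken toward higher sensitivity), and sensitivity, specificity, PPV and
#' the confusion matrix are reported there.
#'
#' @param scores Numeric scores, higher = more likely positive.
#' @param truth Labels aligned with `scores` (factor or character); must
#'   contain both classes.
#' @param positive The positive-class label.
#' @param spec_target Target specificity for the operating point.
#' @return A `classifier_report`: list with `auc_roc`, `auc_pr`,
#'   `sensitivity`, `specificity`, `ppv`, `threshold`, `confusion` (2x2 counts,
#'   predicted x truth), curve tibbles `roc` and `pr`, and counts.
#' @export
evaluate_scores <- function(scores, truth, positive, spec_target = 0.70) {
  truth <- as.character(truth)
  if (length(scores) != length(truth)) abort("`scores` and `truth` must align.")
  is_pos <- truth == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("`truth` must contain both positive and negative samples.")
  }
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sweep_tbl <- purrr::map_dfr(thresholds, function(t) {
    pred_pos <- scores >= t
    tp <- sum(pred_pos & is_pos); fp <- sum(pred_pos & !is_pos)
    tibble(threshold = t, tpr = tp / n_pos, fpr = fp / n_neg,
           precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  })
  auc_roc <- trapz(sweep_tbl$fpr, sweep_tbl$tpr)
  pr_tbl <- sweep_tbl[!is.na(sweep_tbl$precision), ]
  ## anchor recall 0 at the earliest defined precision
  pr <- tibble(recall = c(0, pr_tbl$tpr), precision = c(pr_tbl$precision[1],
                                                        pr_tbl$precision))
  auc_pr <- trapz(pr$recall, pr$precision)

  spec <- 1 - sweep_tbl$fpr
  ok <- which(spec >= spec_target)
  best <- ok[order(spec[ok], -sweep_tbl$tpr[ok])][1]
  thr <- sweep_tbl$threshold[best]
  pred <- factor(ifelse(scores >= thr, positive, paste0("not_", positive)),
                 levels = c(positive, paste0("not_", positive)))
  truth_f <- factor(ifelse(is_pos, positive, paste0("not_", positive)),
                    levels = levels(pred))
  confusion <- table(predicted = pred, truth = truth_f)
  tp <- confusion[1, 1]; fp <- confusion[1, 2]
  structure(list(
    auc_roc = auc_roc, auc_pr = auc_pr,
    sensitivity = sweep_tbl$tpr[best], specificity = spec[best],
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    threshold = thr, confusion = unclass(confusion),
    roc = dplyr::mutate(sweep_tbl, sensitivity = .data$tpr,
                        specificity = 1 - .data$fpr),
    pr = pr, positive = positive, n_pos = n_pos, n_neg = n_neg,
    spec_target = spec_target
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report> positive = ", x$positive,
      " (n = ", x$n_pos, " vs ", x$n_neg, ")\n", sep = "")
  cat(sprintf("  AUC-ROC %.3f | AUC-PR %.3f\n", x$auc_roc, x$auc_pr))
  cat(sprintf("  at specificity target %.0f%%: sensitivity %.1f%%, specificity %.1f%%, PPV %.1f%%\n",
              100 * x$spec_target, 100 * x$sensitivity, 100 * x$specificity,
              100 * x$ppv))
  invisible(x)
}

#' Positive predictive value from rates and class counts
#'
#' `TP = round(sens * n_pos)`, `FP = n_neg - round(spec * n_neg)`,
#' `PPV = TP / (TP + FP)` — the arithmetic that combines a screening test's
#' operating point with the evaluated set's composition (e.g. a 70%/90%
#' operating point on 10 cases and 10 controls gives 7 / (7 + 1) = 87.5%).
#'
#' @param sensitivity,specificity Rates in \[0, 1\].
#' @param n_pos,n_neg Nonnegative class counts.
#' @return The PPV; errors when no sample is called positive (TP + FP = 0).
#' @export
ppv <- function(sensitivity, specificity, n_pos, n_neg) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    abort("Rates must lie in [0, 1].")
  }
  if (n_pos < 0 || n_neg < 0) abort("Counts must be >= 0.")
  tp <- round(sensitivity * n_pos)
  fp <- n_neg - round(specificity * n_neg)
  if (tp + fp == 0) abort("PPV undefined: no sample is called positive (TP + FP = 0).")
  tp / (tp + fp)
}

#' Weighted (balanced) accuracy of a confusion matrix
#'
#' The mean of per-class recalls, so each class contributes equally regardless
#' of prevalence; 1/3 indicates random performance for three classes.
#'
#' @param confusion Square nonnegative count matrix, true classes in rows.
#' @return Weighted accuracy in \[0, 1\].
#' @export
weighted_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) abort("Confusion matrix must be square.")
  rs <- rowSums(confusion)
  if (any(rs == 0)) {
    abort(paste0("Empty true-class row(s): ",
                 paste(rownames(confusion)[rs == 0] %||% which(rs == 0),
                       collapse = ", ")))
  }
  mean(diag(confusion) / rs)
}
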