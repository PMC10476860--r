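#' Tidy a classifier report into curve points
#'
#' @param x A `classifier_report`.
#' @param ... Ignored.
#' @return Tibble of ROC and PR curve points with a `curve` column.
#' @method tidy classifier_report
#' @export
tidy.classifier_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::select(x$roc, x = "fpr", y = "tpr", "threshold"),
                  curve = "roc"),
    dplyr::mutate(dplyr::select(x$pr, x = "recall", y = "precision"),
                  threshold = NA_real_, curve = "pr")
  )
}

#' One-row summary of a classifier report
#'
#' @param x A `classifier_report`.
#' @param ... Ignored.
#' @return One-row tibble with AUCs and operating-point rates.
#' @method glance classifier_report
#' @export
glance.classifier_report <- function(x, ...) {
  tibble(auc_roc = x$auc_roc, auc_pr = x$auc_pr,
         sensitivity = x$sensitivity, specificity = x$specificity,
         ppv = x$ppv, threshold = x$threshold,
         n_pos = x$n_pos, n_neg = x$n_neg, positive = x$positive)
}

#' Tidy a PCoA result into per-sample coordinates
#'
#' @param x A `pcoa_result`.
#' @param ... Ignored.
#' @return Tibble of sample coordinates.
#' @method tidy pcoa_result
#' @export
tidy.pcoa_result <- function(x, ...) {
  x$points
}

#' One-row summary of a PCoA result
#'
#' @param x A `pcoa_result`.
#' @param ... Ignored.
#' @return One-row tibble with axis count and leading variance fractions.
#' @method glance pcoa_result
#' @export
glance.pcoa_result <- function(x, ...) {
  tibble(n_axes = length(x$fractions),
         pco1_fraction = x$fractions[1] %||% NA_real_,
         pco2_fraction = if (length(x$fractions) >= 2) x$fractions[2] else NA_real_,
         total_positive_variance = sum(x$eigenvalues[x$eigenvalues > 0]))
}

#' Tidy a three-class report into per-class recalls
#'
#' @param x A `three_class_report`.
#' @param ... Ignored.
#' @return Tibble with one row per class.
#' @method tidy three_class_report
#' @export
tidy.three_class_report <- function(x, ...) {
  tibble(class = names(x$per_class_recall),
         recall = unname(x$per_class_recall),
         n = unname(rowSums(x$confusion)))
}

#' One-row summary of a three-class report
#'
#' @param x A `three_class_report`.
#' @param ... Ignored.
#' @return One-row tibble with the weighted accuracy.
#' @method glance three_class_report
#' @export
glance.three_class_report <- function(x, ...) {
  tibble(weighted_accuracy = x$weighted_accuracy,
         n = sum(x$confusion), validation = x$validation)
}
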