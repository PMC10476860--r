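#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_point
#'   geom_col coord_equal labs theme_minimal scale_color_brewer
NULL

#' @export
ggplot2::autoplot

#' ROC and precision-recall curves of a classifier report
#'
#' @param object A `classifier_report`.
#' @param which `"roc"` or `"pr"`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot classifier_report
#' @export
autoplot.classifier_report <- function(object, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
      geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                  color = "grey60") +
      geom_line(color = "#2166ac", linewidth = 0.8) +
      coord_equal() +
      labs(x = "1 - specificity", y = "Sensitivity",
           title = sprintf("ROC (AUC = %.3f)", object$auc_roc),
           subtitle = sprintf("positive class: %s", object$positive)) +
      theme_minimal()
  } else {
    ggplot(object$pr, aes(x = .data$recall, y = .data$precision)) +
      geom_line(color = "#b2182b", linewidth = 0.8) +
      labs(x = "Recall", y = "Precision",
           title = sprintf("Precision-recall (AUC = %.3f)", object$auc_pr)) +
      theme_minimal()
  }
}

#' Ordination plot of a PCoA result
#'
#' @param object A `pcoa_result`.
#' @param labels Optional named vector or factor of group labels (indexed by
#'   sample id) to color points.
#' @param axes Which two axes to draw.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot pcoa_result
#' @export
autoplot.pcoa_result <- function(object, labels = NULL, axes = c(1, 2), ...) {
  pts <- object$points
  ax <- paste0("PCo", axes)
  if (!all(ax %in% names(pts))) abort("Requested axes not present in the embedding.")
  if (!is.null(labels)) {
    pts$group <- if (!is.null(names(labels))) labels[pts$sample_id] else labels
  }
  pct <- 100 * object$fractions[axes]
  p <- ggplot(pts, aes(x = .data[[ax[1]]], y = .data[[ax[2]]])) +
    labs(x = sprintf("%s (%.1f%%)", ax[1], pct[1]),
         y = sprintf("%s (%.1f%%)", ax[2], pct[2])) +
    theme_minimal()
  if (is.null(labels)) p + geom_point(alpha = 0.8)
  else p + geom_point(aes(color = .data$group), alpha = 0.8) +
    scale_color_brewer(palette = "Set1")
}

#' Signed-importance bar chart of a marker panel
#'
#' Positive bars indicate compounds with higher relative abundance in the
#' positive (advanced adenoma) class; negative bars, higher in controls.
#'
#' @param object A `marker_panel`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot marker_panel
#' @export
autoplot.marker_panel <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      feature = factor(.data$feature,
                                       levels = rev(.data$feature)))
  ggplot(df, aes(x = .data$signed_importance, y = .data$feature,
                 fill = .data$signed_importance > 0)) +
    geom_col(show.legend = FALSE) +
    labs(x = "Signed mean importance", y = NULL,
         title = "Selected marker compounds") +
    theme_minimal()
}
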