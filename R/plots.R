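# ggplot2 display methods.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#' @param object an `nm_roc`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.nm_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::annotate("point",
                      x = 1 - object$specificity, y = object$sensitivity,
                      shape = 21, size = 3, fill = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s: AUC %.3f (95%% CI %.3f-%.3f)", object$region,
                      object$auc, object$ci[1], object$ci[2]),
      x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Box-and-whisker plot of contrast ratios by group
#'
#' @param cr_table an `nm_cr_table`.
#' @param regions region columns to show.
#' @return a ggplot.
#' @export
plot_cr_distribution <- function(cr_table, regions = cr_regions()) {
  long <- tidyr::pivot_longer(cr_table[, c("group", regions)],
                              dplyr::all_of(regions),
                              names_to = "region", values_to = "cr")
  long$region <- factor(long$region, levels = regions)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$region, y = .data$cr,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "contrast ratio", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Axial montage of a statistic map
#'
#' Shows `-log10(p_corrected)` on axial slices through the analysis mask.
#'
#' @param object an `nm_statmap`.
#' @param slices axial (third-axis) slice indices; defaults to the three
#'   central slices of the mask.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.nm_statmap <- function(object, slices = NULL, ...) {
  kz <- unique(arrayInd(which(object$mask), dim(object$mask))[, 3])
  if (is.null(slices)) {
    mid <- stats::median(kz)
    slices <- intersect(round(mid) + c(-2L, 0L, 2L), kz)
  }
  df <- tidy(object)
  df <- df[df$k %in% slices, ]
  df$neglogp <- -log10(df$p_corrected)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$neglogp)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = "-log10 p (FWE)") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
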