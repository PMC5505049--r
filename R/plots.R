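# ggplot2 views of the result objects

#' @export
#' @method autoplot ct_pca
autoplot.ct_pca <- function(object, ...) {
  pct <- 100 * object$explained_variance
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$class_label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
                  y = sprintf("PC2 (%.1f%%)", pct[2]),
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot roc_curve
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("%s (AUC = %.3f)", object$class,
                                  object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot cv_report
autoplot.cv_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics,
                              c("sensitivity", "specificity",
                                "classification_error"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value,
                                     fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(title = sprintf("Leave-one-dog-out CV (%s)",
                                  object$learner),
                  y = NULL, x = NULL) +
    ggplot2::theme_minimal()
}

#' Plot all one-vs-rest ROC curves of a CV report
#'
#' Calibration and cross-validation curves per class, faceted by class.
#'
#' @param report A `cv_report`.
#' @return A ggplot object.
#' @export
plot_roc <- function(report) {
  curves <- cv_roc(report)
  pts <- purrr::map_dfr(seq_len(nrow(curves)), function(i) {
    p <- curves$curve[[i]]$points
    p$class <- curves$class[i]
    p$mode <- curves$mode[i]
    p
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$mode)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Plot a masked or raw CT slice
#'
#' Renders an HU matrix (or the values of a `masked_image`) as a raster;
#' invalid pixels are blank.
#'
#' @param x HU matrix or `masked_image`.
#' @return A ggplot object.
#' @export
plot_slice <- function(x) {
  vals <- if (inherits(x, "masked_image")) x$values else x
  df <- tibble::tibble(row = as.vector(row(vals)),
                       col = as.vector(col(vals)),
                       hu = as.vector(vals))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 na.value = "#00000000") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
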