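#' Heatmap of an index map
#'
#' @param object an `index_map` (Greenness or NDVI); invalid pixels are
#'   blanked.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.index_map <- function(object, ...) {
  v <- object$values
  v[!object$valid_mask] <- NA_real_
  df <- tidyr::expand_grid(row = seq_len(nrow(v)), col = seq_len(ncol(v)))
  df$value <- as.vector(t(v))  # expand_grid varies col fastest
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = object$kind) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s map", object$kind)) +
    ggplot2::theme_minimal()
}

#' Box plot of whole-leaf NDVI by treatment
#'
#' Mirrors the standard presentation of a two-treatment leaf-imaging trial:
#' one box per treatment, optionally split by leaf position.
#'
#' @param records tibble with `mean_ndvi`, `treatment` and optionally
#'   `leaf_position`.
#' @return a ggplot object.
#' @export
plot_ndvi_groups <- function(records) {
  stopifnot(all(c("mean_ndvi", "treatment") %in% names(records)))
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = .data$treatment, y = .data$mean_ndvi,
                                    fill = .data$treatment)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.shape = 21) +
    ggplot2::labs(x = "treatment", y = "whole-leaf mean NDVI") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
  if ("leaf_position" %in% names(records) &&
      length(unique(records$leaf_position)) > 1) {
    p <- p + ggplot2::facet_wrap(~leaf_position)
  }
  p
}

#' Scatter plot of an OLS fit
#'
#' @param object a `leaf_ols` from [ols_fit()].
#' @param ... unused.
#' @return a ggplot object annotated with the fitted line and `R^2`.
#' @export
autoplot.leaf_ols <- function(object, ...) {
  df <- data.frame(x = object$fit$model$x, y = object$fit$model$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$estimate,
                         intercept = object$intercept, colour = "steelblue") +
    ggplot2::labs(subtitle = sprintf("slope = %.3f, R² = %.3f",
                                     object$estimate, object$r_squared)) +
    ggplot2::theme_minimal()
}
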