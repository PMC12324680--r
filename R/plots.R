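# ggplot2 visualisations for field maps, images and group comparisons.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a field map
#'
#' Raster of the axial field (mT) over the transverse plane nearest the
#' region centre.
#'
#' @param object A [field_map()] result.
#' @param component `"Ba"` or `"Br"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coil_field_map <- function(object, component = c("Ba", "Br"), ...) {
  component <- match.arg(component)
  x0 <- object$x[which.min(abs(object$x - stats::median(unique(object$x))))]
  df <- dplyr::filter(object, .data$x == x0)
  df$value <- df[[component]] * 1e3
  ggplot2::ggplot(df, ggplot2::aes(.data$y * 1e3, .data$z * 1e3,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = paste0(component, " (mT)")) +
    ggplot2::labs(
      x = "y (mm)", y = "z (mm)",
      title = sprintf("%s at axial plane x = %.1f mm", component, x0 * 1e3)
    )
}

#' Plot a grayscale image
#'
#' @param object A `gray_image`.
#' @param ... Unused.
#' @return A ggplot raster of the image.
#' @export
autoplot.gray_image <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$intensity <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Violin plot of a two-group score comparison
#'
#' Violin shapes (truncated at zero, the score floor) with individual
#' values, group means (circles) and medians (crosses), annotated with the
#' two-sided Mann-Whitney p value.
#'
#' @param object A [mann_whitney()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$group, .data$value)) +
    ggplot2::geom_violin(fill = "grey85", trim = TRUE) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 1, size = 3) +
    ggplot2::stat_summary(fun = stats::median, geom = "point", shape = 4,
                          size = 3) +
    ggplot2::expand_limits(y = 0) +
    ggplot2::labs(
      y = "alignment score (%)",
      subtitle = sprintf("Mann-Whitney two-sided p = %.4g", object$p_value)
    )
}
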