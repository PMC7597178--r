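#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an embedded point set
#'
#' Scatter plot of the first two embedding coordinates; clustered points
#' indicate an organized network, a diffuse cloud indicates near-randomness.
#'
#' @param object a `geme_points` object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.geme_points <- function(object, ...) {
  df <- tidy(object)
  if (object$k < 2L) df$x2 <- 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x1, y = .data$x2)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "embedding axis 1", y = "embedding axis 2",
                  title = sprintf("Embedded point pattern (n = %d, k = %d)",
                                  ncol(object$coordinates), object$k)) +
    ggplot2::theme_minimal()
}

#' Plot an estimated K curve against the spatial-randomness reference
#'
#' Draws the edge-corrected K estimate over the radii grid together with the
#' planar complete-spatial-randomness reference `pi r^2` (shown for 2-D
#' patterns); excess over the reference at small radii signals clustering.
#'
#' @param object a `geme_kcurve` (or `geme_result`, whose curve is drawn).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.geme_kcurve <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$k_hat)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "radius r", y = expression(hat(K)(r)),
                  title = sprintf("Ripley K curve (%s correction)",
                                  object$correction)) +
    ggplot2::theme_minimal()
  p + ggplot2::geom_line(ggplot2::aes(y = pi * .data$r^2),
                         linetype = "dashed", colour = "grey50")
}

#' @rdname autoplot.geme_kcurve
#' @export
autoplot.geme_result <- function(object, ...) autoplot(object$curve, ...)

#' Heatmap of a power grid
#'
#' @param grid tibble from [power_grid()].
#' @return a ggplot tile map of estimated power by group-two correlations
#'   (rows) and block sizes (columns).
#' @export
plot_power_grid <- function(grid) {
  stopifnot(all(c("correlations", "sizes", "power") %in% names(grid)))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$sizes, y = .data$correlations,
                                     fill = .data$power)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f%%", 100 * .data$power)), colour = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "power") +
    ggplot2::labs(x = "group-two block sizes", y = "group-two correlations",
                  title = "Estimated power of the two-group Geme test") +
    ggplot2::theme_minimal()
}
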