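#' Plot an analyzed image with its geometry overlay
#'
#' Renders the B-mode image with the aponeurosis linear fits and every
#' accepted fascicle's extrapolated segment between its two intersection
#' points.
#'
#' @param object A `muscle_architecture` result (with the image passed via
#'   `image =`, since results do not retain pixels).
#' @param image The [bmode_image()] that was analyzed.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.muscle_architecture <- function(object, image = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(image)) {
    px <- image$pixels
    df <- tidyr::expand_grid(y = 0:(nrow(px) - 1), x = 0:(ncol(px) - 1))
    df$value <- as.vector(t(px))
    p <- p + ggplot2::geom_raster(data = df,
                                  ggplot2::aes(.data$x, .data$y,
                                               fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   guide = "none")
  }
  for (role in c("superficial", "deep")) {
    ap <- object$aponeuroses[[role]]
    xs <- seq(ap$x_extent[1], ap$x_extent[2], length.out = 50)
    p <- p + ggplot2::geom_line(
      data = data.frame(x = xs, y = eval_quadratic(ap$quadratic, xs)),
      ggplot2::aes(.data$x, .data$y), color = "cyan", linewidth = 0.6)
  }
  if (nrow(object$fascicles)) {
    p <- p + ggplot2::geom_segment(
      data = object$fascicles,
      ggplot2::aes(x = .data$x_superficial, y = .data$y_superficial,
                   xend = .data$x_deep, yend = .data$y_deep),
      color = "yellow", linewidth = 0.4)
  }
  p + ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$image_id, x = "x (px)", y = "depth (px)") +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Classic mean-difference plot with the bias (solid line) and limits of
#' agreement (dashed lines).
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- data.frame(mean = object$means, difference = object$differences)
  ggplot2::ggplot(df, ggplot2::aes(.data$mean, .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods", y = "Difference (method1 - method2)",
                  title = sprintf("Bias %.3f, LoA [%.3f, %.3f]",
                                  object$bias, object$loa_low,
                                  object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Dot-and-interval plot of a reliability report's ICCs
#'
#' @param report A [reliability_report()].
#' @return A ggplot object.
#' @export
plot_reliability <- function(report) {
  df <- report$icc
  ggplot2::ggplot(df, ggplot2::aes(.data$intensity, .data$estimate,
                                   color = .data$method,
                                   shape = .data$contrast)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_hline(yintercept = c(0.5, 0.75, 0.9), linetype = "dotted") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(y = "ICC (95% CI)", x = "Contraction intensity") +
    ggplot2::theme_minimal()
}
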