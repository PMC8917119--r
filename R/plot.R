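#' Double-angle plot of astigmatism prediction errors
#'
#' The classic presentation for astigmatic outcomes: each eye's error
#' vector is drawn in double-angle space (axis doubled, magnitude as
#' radius), with concentric magnitude rings, the centroid, and the 95%
#' confidence ellipses of the dataset (where individual eyes fall) and of
#' the centroid (uncertainty of the mean).  Rim labels mark the clinical
#' axis, i.e. half the plotted angle.
#'
#' @param errors Data frame with double-angle columns `x`, `y` (diopters).
#' @param level Ellipse confidence level (default 0.95); ellipses need
#'   `n >= 3` and are omitted below that.
#' @param ring_step Spacing of the magnitude rings in diopters.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
render_double_angle_plot <- function(errors, level = 0.95, ring_step = 0.5,
                                     title = NULL) {
  n <- nrow(errors)
  max_r <- max(c(sqrt(errors$x^2 + errors$y^2), ring_step), na.rm = TRUE)
  rings <- seq(ring_step, ceiling(max_r / ring_step) * ring_step, by = ring_step)
  t <- seq(0, 2 * pi, length.out = 181)
  ring_df <- dplyr::bind_rows(lapply(rings, function(r) {
    tibble::tibble(r = r, x = r * cos(t), y = r * sin(t))
  }))
  lim <- max(rings)
  lab_df <- tibble::tibble(angle = c(0, 90, 180, 270),
                           label = c("0°", "45°", "90°", "135°"),
                           x = 1.12 * lim * cos(c(0, 90, 180, 270) * pi / 180),
                           y = 1.12 * lim * sin(c(0, 90, 180, 270) * pi / 180))
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = ring_df,
                       ggplot2::aes(x = .data$x, y = .data$y, group = .data$r),
                       color = "grey80", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, color = "grey80", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, color = "grey80", linewidth = 0.3) +
    ggplot2::geom_text(data = lab_df,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
                       size = 3, color = "grey40")
  if (n > 0) {
    p <- p + ggplot2::geom_point(data = errors,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 color = "grey25", size = 1.4, alpha = 0.8)
  }
  caption <- sprintf("n = %d", n)
  if (n >= 3) {
    ds <- confidence_ellipse(errors$x, errors$y, level, "dataset")
    ce <- confidence_ellipse(errors$x, errors$y, level, "centroid")
    cen <- from_double_angle(mean(errors$x), mean(errors$y))
    p <- p +
      ggplot2::geom_path(data = ellipse_outline(ds),
                         ggplot2::aes(x = .data$x, y = .data$y),
                         color = "blue", linewidth = 0.5) +
      ggplot2::geom_path(data = ellipse_outline(ce),
                         ggplot2::aes(x = .data$x, y = .data$y),
                         color = "red", linewidth = 0.5) +
      ggplot2::annotate("point", x = mean(errors$x), y = mean(errors$y),
                        shape = 3, size = 3, color = "red")
    caption <- sprintf("n = %d; centroid %.2f D @ %.0f°",
                       n, cen$magnitude, cen$axis)
  }
  p +
    ggplot2::coord_equal(xlim = c(-1.2, 1.2) * lim, ylim = c(-1.2, 1.2) * lim) +
    ggplot2::labs(title = title, caption = caption,
                  x = "x (D)", y = "y (D)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' Save a ggplot as SVG
#'
#' Uses the cairo-backed `grDevices::svg()` device, so no extra graphics
#' packages are needed.
#'
#' @param plot A ggplot object.
#' @param path Output path ending in `.svg`.
#' @param width,height Inches.
#' @return `path`, invisibly.
#' @export
save_svg <- function(plot, path, width = 5, height = 5) {
  grDevices::svg(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(plot)
  invisible(path)
}
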