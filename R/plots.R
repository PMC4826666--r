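#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a plaque geometry
#'
#' Draws the lumen, intima--media interface and outer wall contours with
#' any calcified regions, in the ultrasound convention (axial depth
#' increasing downwards).
#'
#' @param object A `plaque_geometry`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plaque_geometry <- function(object, ...) {
  close_ring <- function(df) df[c(seq_len(nrow(df)), 1L), ]
  layers <- dplyr::bind_rows(
    dplyr::mutate(close_ring(object$outer), contour = "outer wall"),
    dplyr::mutate(close_ring(object$ima), contour = "intima-media interface"),
    dplyr::mutate(close_ring(object$lumen), contour = "lumen"))
  p <- ggplot2::ggplot(layers, ggplot2::aes(.data$x, .data$y,
                                            colour = .data$contour)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "lateral x (mm)", y = "axial depth y (mm)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  for (cal in object$calcium)
    p <- p + ggplot2::geom_polygon(data = close_ring(cal),
                                   ggplot2::aes(.data$x, .data$y),
                                   inherit.aes = FALSE,
                                   fill = "grey40", alpha = 0.7)
  p
}

#' Plot a displacement map
#'
#' @param object A `displacement_map`.
#' @param component `"axial"` or `"lateral"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.displacement_map <- function(object, component = c("axial", "lateral"),
                                      ...) {
  component <- match.arg(component)
  m <- if (component == "axial") object$axial_um else object$lateral_um
  df <- tidyr::expand_grid(x_mm = object$x_mm, y_mm = object$y_mm)
  df <- df[order(df$x_mm, df$y_mm), ]
  df$u_um <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$u_um)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral x (mm)", y = "axial depth y (mm)",
                  fill = paste0(component, " u (µm)")) +
    ggplot2::theme_minimal()
}

#' Plot a B-mode image
#'
#' @param object A `bmode_image`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bmode_image <- function(object, ...) {
  x0 <- attr(object, "x0_mm")
  df <- tidyr::expand_grid(
    x_mm = x0 + (seq_len(ncol(object)) - 1L) * attr(object, "line_pitch_um") / 1000,
    y_mm = (seq_len(nrow(object)) - 1L) * attr(object, "axial_step_um") / 1000)
  df <- df[order(df$x_mm, df$y_mm), ]
  df$intensity <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral x (mm)", y = "axial depth y (mm)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-step stiffness estimates
#'
#' Young's moduli of wall and intima across the three incremental pressure
#' steps.
#'
#' @param object A `stiffness_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stiffness_estimate <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$step), .data$E,
                                   colour = .data$component,
                                   group = .data$component)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "pressure step", y = "Young's modulus E (kPa)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
print.plaque_geometry <- function(x, ...) {
  cat("<plaque_geometry>",
      if (isTRUE(x$eccentric)) "eccentric" else "concentric", "plaque\n")
  cat(sprintf("  lumen area %.2f mm^2, tissue area %.2f mm^2, %d calcium region(s)\n",
              polygon_area(x$lumen),
              polygon_area(x$outer) - polygon_area(x$lumen),
              length(x$calcium)))
  invisible(x)
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d samples x %d lines (%.4g um axial step, %g um pitch, %g MHz)\n",
              nrow(x$samples), ncol(x$samples), x$axial_step_um,
              x$line_pitch_um, x$transducer$center_frequency))
  invisible(x)
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("<fe_solution> %g mmHg (%.4g kPa gauge): max |u| = %.4g mm, %d Newton iterations\n",
              x$pressure_mmHg, x$pressure_kPa, max(abs(x$U)),
              x$newton_iterations))
  invisible(x)
}
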