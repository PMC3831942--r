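#' Plot a diffraction frame
#'
#' Raster view of one frame (square-root intensity scale), optionally with
#' predicted reflection positions circled.
#'
#' @param series A `microed_series`.
#' @param frame Frame index.
#' @param predictions Optional tibble with `x, y` columns to overlay.
#' @param downsample Integer pixel-binning factor for display only.
#' @return A ggplot object.
#' @export
plot_frame <- function(series, frame, predictions = NULL, downsample = 2) {
  img <- get_frame(series, frame)
  ds <- max(1L, as.integer(downsample))
  ii <- seq(1, nrow(img), by = ds); jj <- seq(1, ncol(img), by = ds)
  df <- expand.grid(y = ii - 1, x = jj - 1)
  df$value <- as.vector(img[ii, jj])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = sqrt(pmax(.data$value, 0)))) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "sqrt(counts)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("frame %d (tilt %g deg)",
                                  frame, series$meta$tilt[frame]),
                  x = "x (px)", y = "y (px)")
  if (!is.null(predictions) && nrow(predictions)) {
    p <- p + ggplot2::geom_point(data = predictions,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 shape = 1, colour = "red", size = 2)
  }
  p
}

#' @rdname critical_dose
#' @param object A `microed_dose_fit`.
#' @param ... Unused.
#' @export
autoplot.microed_dose_fit <- function(object, ...) {
  df <- object$data
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$intensity)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(x = "cumulative dose (e-/A^2)", y = "normalized intensity")
  if (object$decay_detected) {
    grid <- tibble::tibble(dose = seq(min(df$dose), max(df$dose),
                                      length.out = 200))
    grid$fit <- object$plateau -
      object$decay_rate * pmax(0, grid$dose - object$critical_dose)
    p <- p +
      ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                         colour = "red") +
      ggplot2::geom_vline(xintercept = object$critical_dose,
                          linetype = "dashed")
  }
  p
}

#' Shell-completeness plot for a merged set
#'
#' @param object A `microed_merged` with an attached cell.
#' @param dmax,dmin Resolution range (A).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.microed_merged <- function(object, dmax = 20, dmin = 2.9, ...) {
  st <- completeness_stats(object, dmax = dmax, dmin = dmin)
  sh <- st$shells
  ggplot2::ggplot(sh, ggplot2::aes(x = .data$d_high,
                                   y = 100 * .data$completeness)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "shell resolution d (A)", y = "completeness (%)",
                  title = sprintf("overall completeness %.1f%%",
                                  100 * st$completeness))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
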