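# ggplot2 helpers for quick visual checks of detections, measurements, and
# agreement with ground truth.

#' Plot detections over an image
#'
#' @param image RGB image array (drawn as a raster backdrop).
#' @param d Detection tibble (rectangles colored by confidence).
#' @return A ggplot object.
#' @export
plot_detections <- function(image, d) {
  image <- clamp(as_image_array(image), 0, 1)
  H <- nrow(image); W <- ncol(image)
  rast <- grDevices::as.raster(image)
  ggplot2::ggplot(d) +
    ggplot2::annotation_raster(rast, xmin = 0, xmax = W, ymin = -H, ymax = 0) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                   ymin = -.data$y_max, ymax = -.data$y_min,
                   color = .data$confidence),
      fill = NA, linewidth = 0.3
    ) +
    ggplot2::scale_color_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed(xlim = c(0, W), ylim = c(-H, 0), expand = FALSE) +
    ggplot2::labs(x = "column (px)", y = "row (px)", color = "conf") +
    ggplot2::theme_minimal()
}

#' Plot a skeleton and its main path
#'
#' @param sk Logical skeleton matrix.
#' @param path Optional `skeleton_path` highlighted in red.
#' @return A ggplot object.
#' @export
plot_skeleton <- function(sk, path = NULL) {
  px <- which(sk, arr.ind = TRUE)
  df <- tibble::tibble(row = px[, 1] - 1, col = px[, 2] - 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::geom_point(size = 0.2, color = "grey40") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
  if (!is.null(path) && isTRUE(path$reachable)) {
    pdf_ <- tibble::tibble(row = path$pixels[, 1], col = path$pixels[, 2])
    p <- p + ggplot2::geom_path(data = pdf_, color = "red", linewidth = 0.6)
  }
  p
}

#' Actual-vs-forecast scatter with the identity line
#'
#' @param actual,forecast Numeric vectors of equal length.
#' @param label Axis label for the trait.
#' @return A ggplot object annotated with R^2 and MAPE.
#' @export
plot_agreement <- function(actual, forecast, label = "value") {
  df <- tibble::tibble(actual = actual, forecast = forecast)
  sub <- sprintf("R² = %.3f, MAPE = %.2f%%",
                 r_squared(actual, forecast), mape(actual, forecast))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$actual, y = .data$forecast)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = paste("actual", label), y = paste("forecast", label),
                  subtitle = sub) +
    ggplot2::theme_minimal()
}
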