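#' Locate the red circular calibrator in a panicle image
#'
#' Every panicle photograph includes a red disk of known physical radius
#' against the background board. This function classifies red pixels in HSV
#' space, labels connected components, and returns the largest red component
#' as the calibrator. The pixel radius is the radius of the equal-area
#' circle, `sqrt(area / pi)`, which is robust to ragged component edges.
#'
#' @param image RGB image array `[row, col, channel]` in `[0, 1]`.
#' @param color_range Named list of HSV bounds for "red": `hue_low` and
#'   `hue_high` (degrees; red wraps around 0 so pixels with hue <=
#'   `hue_low` or >= `hue_high` qualify), `sat_min`, `val_min`.
#' @param min_area Minimum component area in px^2 considered a candidate.
#' @return An object of class `calibrator_detection`: a list with `center`
#'   (0-based `(row, col)` of the component centroid), `pixel_radius`, and
#'   `mask` (logical matrix of the calibrator region).
#' @seealso [pel_density()]
#' @export
detect_calibrator <- function(image,
                              color_range = list(hue_low = 10, hue_high = 350,
                                                 sat_min = 0.4, val_min = 0.2),
                              min_area = 200) {
  image <- as_image_array(image)
  hsv <- image_hsv(image)
  red <- (hsv$h <= color_range$hue_low | hsv$h >= color_range$hue_high) &
    hsv$s >= color_range$sat_min & hsv$v >= color_range$val_min
  if (!any(red)) stopf("calibrator not found: no red pixels")
  lab <- label_components(red)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  if (length(keep) == 0L) stopf("calibrator not found: no red component with area >= %g", min_area)
  big <- keep[which.max(areas[keep])]
  rivals <- setdiff(keep[areas[keep] >= 0.8 * areas[big]], big)
  if (length(rivals) > 0L) {
    stopf("ambiguous calibrator: %d red components within 20%% of the largest's area",
          length(rivals) + 1L)
  }
  mask <- lab == big
  px <- which(mask, arr.ind = TRUE)
  structure(
    list(
      center = c(row = mean(px[, 1]) - 0.5, col = mean(px[, 2]) - 0.5),
      pixel_radius = sqrt(areas[big] / pi),
      mask = mask
    ),
    class = "calibrator_detection"
  )
}

#' Compute the pel density (mm per pixel) from the calibrator radius
#'
#' The pel density is the physical size represented by one image pixel. With
#' a calibrator of known real radius (25 mm by protocol), it is simply
#' `real_radius_mm / pixel_radius`. All downstream pixel measurements (grain
#' length/width, panicle length) are multiplied by `mm_per_pixel` to obtain
#' millimetres, which makes the physical traits invariant to the shooting
#' distance.
#'
#' @param pixel_radius Calibrator radius in pixels (> 0), e.g. from
#'   [detect_calibrator()].
#' @param real_radius_mm Real-world calibrator radius in mm (default 25).
#' @return An object of class `pel_density`: list with `mm_per_pixel`,
#'   `real_radius_mm`, `pixel_radius`.
#' @examples
#' pel_density(125)$mm_per_pixel  # 0.2
#' @export
pel_density <- function(pixel_radius, real_radius_mm = 25) {
  if (inherits(pixel_radius, "calibrator_detection")) {
    pixel_radius <- pixel_radius$pixel_radius
  }
  if (!is.numeric(pixel_radius) || length(pixel_radius) != 1L || pixel_radius <= 0) {
    stopf("pixel_radius must be a single positive number")
  }
  if (real_radius_mm <= 0) stopf("real_radius_mm must be positive")
  structure(
    list(
      mm_per_pixel = real_radius_mm / pixel_radius,
      real_radius_mm = real_radius_mm,
      pixel_radius = pixel_radius
    ),
    class = "pel_density"
  )
}

#' @export
print.pel_density <- function(x, ...) {
  cat(sprintf("<pel_density> %.5f mm/px (calibrator %.2f px = %.1f mm)\n",
              x$mm_per_pixel, x$pixel_radius, x$real_radius_mm))
  invisible(x)
}

#' One-row tibble export of a calibration result
#'
#' @param image_id Image identifier.
#' @param calibrator A `calibrator_detection`.
#' @param pel A `pel_density`.
#' @return Tibble with columns `image_id`, `pixel_radius`, `mm_per_pixel`.
#' @export
calibration_record <- function(image_id, calibrator, pel) {
  tibble::tibble(
    image_id = image_id,
    pixel_radius = calibrator$pixel_radius,
    mm_per_pixel = pel$mm_per_pixel
  )
}
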