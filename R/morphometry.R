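# Grain morphometry: screen detections for unoccluded grains, crop each
# box, segment the grain body, and measure length/width as the sides of the
# minimum-area rotated bounding rectangle, converted to mm via pel density.
# Only a screened subset of grains is measured; their means represent the
# panicle.

#' Screening configuration for grain morphometry
#'
#' The defaults are the combination found best for grain-length recovery:
#' confidence threshold 0.7, NMS IoU threshold 0.8, no crop padding.
#'
#' @param conf Confidence threshold in `[0, 1]` (default 0.7).
#' @param nms_iou NMS IoU threshold in `[0, 1]` (default 0.8), applied as
#'   detection post-processing.
#' @param pad_pixels Crop padding, 0 or 2 pixels per side (default 0).
#' @param max_pairwise_iou Optional occlusion filter: after NMS and
#'   confidence filtering, drop any box whose IoU with another survivor
#'   exceeds this; 1 disables it (default).
#' @return A `screening_config` list.
#' @export
screening_config <- function(conf = 0.7, nms_iou = 0.8, pad_pixels = 0,
                             max_pairwise_iou = 1.0) {
  stopifnot(conf >= 0, conf <= 1, nms_iou >= 0, nms_iou <= 1,
            pad_pixels %in% c(0, 2),
            max_pairwise_iou >= 0, max_pairwise_iou <= 1)
  structure(list(conf = conf, nms_iou = nms_iou, pad_pixels = pad_pixels,
                 max_pairwise_iou = max_pairwise_iou),
            class = "screening_config")
}

#' Screen detections for measurable (un-occluded) grains
#'
#' Applies [nms()] at `cfg$nms_iou`, then [filter_confidence()] at
#' `cfg$conf`; when `cfg$max_pairwise_iou < 1`, additionally drops every
#' box whose IoU with another surviving box exceeds it. Deterministic.
#'
#' @param d Detection tibble.
#' @param cfg A [screening_config()].
#' @return Screened detection tibble (possibly empty).
#' @export
screen_grains <- function(d, cfg = screening_config()) {
  out <- filter_confidence(nms(d, cfg$nms_iou), cfg$conf)
  if (cfg$max_pairwise_iou < 1 && nrow(out) > 1L) {
    M <- iou_matrix(out)
    diag(M) <- 0
    out <- out[apply(M, 1, max) <= cfg$max_pairwise_iou, , drop = FALSE]
  }
  out
}

#' Crop a grain box out of an image
#'
#' The box is dilated by `pad_pixels` on each side and clipped to the
#' image; the applied offsets are recorded so crop-local coordinates can be
#' mapped back.
#'
#' @param image RGB image array.
#' @param box One-row data frame with `x_min`, `y_min`, `x_max`, `y_max`.
#' @param pad_pixels Padding per side (default 0).
#' @return List with `crop` (RGB array) and `offset` (`(row, col)` 0-based
#'   position of the crop's top-left pixel in the image).
#' @export
crop_grain <- function(image, box, pad_pixels = 0) {
  image <- as_image_array(image)
  H <- nrow(image); W <- ncol(image)
  x0 <- max(0, floor(box$x_min) - pad_pixels)
  y0 <- max(0, floor(box$y_min) - pad_pixels)
  x1 <- min(W, ceiling(box$x_max) + pad_pixels)
  y1 <- min(H, ceiling(box$y_max) + pad_pixels)
  if (x1 <= x0 || y1 <= y0) stopf("box lies fully outside the image")
  list(
    crop = image[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE],
    offset = c(row = y0, col = x0)
  )
}

#' Segment the grain body inside a crop
#'
#' Threshold segmentation followed by particle filtering: the crop is
#' thresholded (Otsu on the brightness channel by default, or a fixed RGB
#' window) and only the largest connected component — the grain's main
#' body — is kept.
#'
#' @param crop RGB crop array.
#' @param method `"otsu"` or `"rgb_range"`.
#' @param rgb_lo,rgb_hi RGB window for `method = "rgb_range"`.
#' @return Logical mask of the grain body.
#' @export
segment_grain <- function(crop, method = c("otsu", "rgb_range"),
                          rgb_lo = c(0.72, 0.55, 0.15),
                          rgb_hi = c(1.00, 0.90, 0.60)) {
  method <- match.arg(method)
  crop <- as_image_array(crop)
  if (method == "otsu") {
    v <- pmax(crop[, , 1], crop[, , 2], crop[, , 3])
    fg <- v > otsu_threshold(v)
  } else {
    fg <- crop[, , 1] >= rgb_lo[1] & crop[, , 1] <= rgb_hi[1] &
      crop[, , 2] >= rgb_lo[2] & crop[, , 2] <= rgb_hi[2] &
      crop[, , 3] >= rgb_lo[3] & crop[, , 3] <= rgb_hi[3]
  }
  if (!any(fg)) stopf("no grain body: empty foreground after thresholding")
  lab <- label_components(fg)
  areas <- tabulate(lab[lab > 0L])
  lab == which.max(areas)
}

#' Minimum-area rotated bounding rectangle of a binary mask
#'
#' Foreground pixels are treated as unit squares (their corners enter the
#' convex hull), so an axis-aligned `w x h` block measures exactly
#' `(w, h)`. The minimum-area enclosing rectangle is found by rotating
#' calipers over the hull edges. The longer side is the length.
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @return List with `length_px`, `width_px`, `angle` (degrees in
#'   `[0, 180)`, orientation of the long side measured from the column
#'   axis), and `area` of the rectangle.
#' @export
min_bounding_rect <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) == 0L) stopf("empty mask")
  r <- px[, 1]; c <- px[, 2]
  x <- c(c - 1, c, c - 1, c)
  y <- c(r - 1, r - 1, r, r)
  pts <- unique(cbind(x, y))
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  n <- length(h)
  ex <- hx[c(2:n, 1)] - hx
  ey <- hy[c(2:n, 1)] - hy
  len <- sqrt(ex^2 + ey^2)
  ok <- len > 0
  ux <- ex[ok] / len[ok]; uy <- ey[ok] / len[ok]
  best <- list(area = Inf)
  for (i in seq_along(ux)) {
    p <- hx * ux[i] + hy * uy[i]        # along the edge
    q <- -hx * uy[i] + hy * ux[i]       # perpendicular
    d1 <- max(p) - min(p)
    d2 <- max(q) - min(q)
    a <- d1 * d2
    if (a < best$area - 1e-12) {
      ang <- atan2(uy[i], ux[i])
      if (d1 >= d2) {
        best <- list(area = a, length = d1, width = d2, angle = ang)
      } else {
        best <- list(area = a, length = d2, width = d1, angle = ang + pi / 2)
      }
    }
  }
  angle <- (best$angle * 180 / pi) %% 180
  list(length_px = best$length, width_px = best$width,
       angle = angle, area = best$area)
}

#' Measure screened grains in physical units
#'
#' The full morphometry chain: [screen_grains()] selects un-occluded
#' grains, each is cropped ([crop_grain()]), segmented
#' ([segment_grain()]), boxed by [min_bounding_rect()], and converted to
#' mm with the pel density. Grains whose segmentation fails are skipped
#' and tallied in the `skipped` attribute.
#'
#' @param image RGB image array.
#' @param d Detection tibble.
#' @param cfg A [screening_config()].
#' @param pel A [pel_density()].
#' @param segment_method Passed to [segment_grain()].
#' @param rgb_lo,rgb_hi Passed to [segment_grain()] for `"rgb_range"`.
#' @return Tibble with one row per measured grain: `image_id`, box
#'   corners, `length_px`, `width_px`, `angle`, `length_mm`, `width_mm`,
#'   `aspect_ratio`. Attribute `skipped` counts segmentation failures.
#' @export
measure_grains <- function(image, d, cfg = screening_config(), pel,
                           segment_method = "otsu",
                           rgb_lo = c(0.72, 0.55, 0.15),
                           rgb_hi = c(1.00, 0.90, 0.60)) {
  stopifnot(inherits(pel, "pel_density"))
  screened <- screen_grains(d, cfg)
  if (nrow(screened) == 0L) stopf("no measurable grains")
  skipped <- 0L
  rows <- purrr::map(seq_len(nrow(screened)), function(i) {
    box <- screened[i, ]
    res <- tryCatch({
      cr <- crop_grain(image, box, cfg$pad_pixels)
      mask <- segment_grain(cr$crop, segment_method, rgb_lo, rgb_hi)
      mbr <- min_bounding_rect(mask)
      tibble::tibble(
        image_id = box$image_id,
        x_min = box$x_min, y_min = box$y_min,
        x_max = box$x_max, y_max = box$y_max,
        confidence = box$confidence,
        length_px = mbr$length_px, width_px = mbr$width_px,
        angle = mbr$angle,
        length_mm = mbr$length_px * pel$mm_per_pixel,
        width_mm = mbr$width_px * pel$mm_per_pixel,
        aspect_ratio = mbr$length_px / mbr$width_px
      )
    }, error = function(e) NULL)
    if (is.null(res)) skipped <<- skipped + 1L
    res
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) stopf("no measurable grains")
  attr(out, "skipped") <- skipped
  out
}

#' Panicle-level grain statistics
#'
#' Arithmetic means of the measured grains represent the whole panicle.
#' The mean aspect ratio is the mean of per-grain aspects (not the ratio
#' of the mean dimensions).
#'
#' @param measurements Tibble from [measure_grains()].
#' @return One-row tibble: `n_measured`, `mean_length_mm`,
#'   `mean_width_mm`, `mean_aspect`.
#' @export
panicle_grain_stats <- function(measurements) {
  if (is.null(measurements) || nrow(measurements) == 0L) {
    stopf("no measurements to aggregate")
  }
  tibble::tibble(
    n_measured = nrow(measurements),
    mean_length_mm = mean(measurements$length_mm),
    mean_width_mm = mean(measurements$width_mm),
    mean_aspect = mean(measurements$aspect_ratio)
  )
}
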