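# Grain detections are tibbles with columns image_id, x_min, y_min, x_max,
# y_max, confidence. Boxes are half-open [min, max) in 0-based pixel
# coordinates (x = column, y = row), so width = x_max - x_min.

#' Build a detection tibble
#'
#' @param x_min,y_min,x_max,y_max Box edges in 0-based half-open pixel
#'   coordinates (x = column, y = row).
#' @param confidence Detector confidences in `[0, 1]`.
#' @param image_id Image identifier (recycled).
#' @param image_size Optional `(H, W)` image size; when given, boxes are
#'   validated against it and the size is stored as the `image_size`
#'   attribute.
#' @return A tibble of detections.
#' @export
detections <- function(x_min = numeric(), y_min = numeric(),
                       x_max = numeric(), y_max = numeric(),
                       confidence = numeric(), image_id = "image",
                       image_size = NULL) {
  d <- tibble::tibble(
    image_id = rep_len(as.character(image_id), length(x_min)),
    x_min = as.numeric(x_min), y_min = as.numeric(y_min),
    x_max = as.numeric(x_max), y_max = as.numeric(y_max),
    confidence = rep_len(as.numeric(confidence), length(x_min))
  )
  validate_detections(d, image_size)
  if (!is.null(image_size)) attr(d, "image_size") <- image_size
  d
}

validate_detections <- function(d, image_size = NULL) {
  req <- c("image_id", "x_min", "y_min", "x_max", "y_max", "confidence")
  miss <- setdiff(req, names(d))
  if (length(miss)) stopf("detections missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(d) == 0L) return(invisible(d))
  bad <- which(d$x_max <= d$x_min | d$y_max <= d$y_min)
  if (length(bad)) stopf("invalid box at row %d: max <= min", bad[1])
  if (any(d$confidence < 0 | d$confidence > 1)) stopf("confidence outside [0, 1]")
  if (!is.null(image_size)) {
    H <- image_size[1]; W <- image_size[2]
    out <- which(d$x_min < 0 | d$y_min < 0 | d$x_max > W | d$y_max > H)
    if (length(out)) stopf("box at row %d lies outside the %dx%d image", out[1], H, W)
  }
  invisible(d)
}

#' Clip detections to image bounds
#'
#' Boxes are clipped to `[0, W) x [0, H)`; boxes that clip to empty are
#' dropped with a warning.
#'
#' @param d Detection tibble.
#' @param image_size `(H, W)` in pixels.
#' @return Clipped detection tibble.
#' @export
clip_detections <- function(d, image_size) {
  H <- image_size[1]; W <- image_size[2]
  d$x_min <- pmax(d$x_min, 0); d$y_min <- pmax(d$y_min, 0)
  d$x_max <- pmin(d$x_max, W); d$y_max <- pmin(d$y_max, H)
  empty <- d$x_max <= d$x_min | d$y_max <= d$y_min
  if (any(empty)) {
    warning(sprintf("dropped %d box(es) clipped to empty", sum(empty)), call. = FALSE)
    d <- d[!empty, , drop = FALSE]
  }
  attr(d, "image_size") <- image_size
  d
}

#' Intersection over union of axis-aligned boxes
#'
#' IoU measures the overlap of two boxes and ranges from 0 (disjoint) to 1
#' (identical). Areas use the half-open convention, so a box's area is
#' `(x_max - x_min) * (y_max - y_min)`.
#'
#' @param a,b Data frames (rows recycled elementwise) with columns `x_min`,
#'   `y_min`, `x_max`, `y_max`.
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @examples
#' box_iou(data.frame(x_min = 0, y_min = 0, x_max = 2, y_max = 2),
#'         data.frame(x_min = 1, y_min = 0, x_max = 3, y_max = 2))  # 1/3
#' @export
box_iou <- function(a, b) {
  iw <- pmax(0, pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min))
  ih <- pmax(0, pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min))
  inter <- iw * ih
  union <- (a$x_max - a$x_min) * (a$y_max - a$y_min) +
    (b$x_max - b$x_min) * (b$y_max - b$y_min) - inter
  ifelse(union > 0, inter / union, 0)
}

# n x m IoU matrix between two detection tables
iou_matrix <- function(a, b = a) {
  n <- nrow(a); m <- nrow(b)
  if (n == 0L || m == 0L) return(matrix(numeric(), n, m))
  ia <- rep(seq_len(n), times = m)
  ib <- rep(seq_len(m), each = n)
  matrix(box_iou(a[ia, , drop = FALSE], b[ib, , drop = FALSE]), n, m)
}

#' Filter detections by confidence threshold
#'
#' Keeps boxes with `confidence >= conf`, preserving order.
#'
#' @param d Detection tibble.
#' @param conf Threshold in `[0, 1]`.
#' @return Filtered detection tibble.
#' @export
filter_confidence <- function(d, conf) {
  stopifnot(conf >= 0, conf <= 1)
  d[d$confidence >= conf, , drop = FALSE]
}

#' Greedy non-maximum suppression
#'
#' Boxes are visited in order of decreasing confidence (ties broken by
#' `x_min` then `y_min` ascending, for determinism); each kept box
#' suppresses all remaining boxes whose IoU with it exceeds
#' `iou_threshold`.
#'
#' @param d Detection tibble.
#' @param iou_threshold Suppression threshold in `[0, 1]`; overlaps
#'   strictly greater than it are suppressed.
#' @return The surviving detections, in visit order.
#' @export
nms <- function(d, iou_threshold) {
  stopifnot(iou_threshold >= 0, iou_threshold <= 1)
  if (nrow(d) <= 1L) return(d)
  ord <- order(-d$confidence, d$x_min, d$y_min)
  d <- d[ord, , drop = FALSE]
  n <- nrow(d)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  M <- iou_matrix(d)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    sup <- alive & M[i, ] > iou_threshold
    sup[i] <- FALSE
    alive[sup] <- FALSE
  }
  d[keep, , drop = FALSE]
}

#' Classical baseline grain detector
#'
#' A trained detector is not required to run the pipeline: this baseline
#' segments grain-colored pixels, labels connected components, splits
#' oversized components (area > `split_factor` x median component area)
#' with a distance-transform watershed, and emits one box per final
#' component. Confidence is the component's solidity (area over convex-hull
#' area), clamped to `[0, 1]` — compact elliptical grains score near 1.
#'
#' @param image RGB image array.
#' @param params List from [detect_params()].
#' @return Detection tibble (possibly empty) with attribute `image_size`.
#' @export
baseline_detect <- function(image, params = detect_params()) {
  image <- as_image_array(image)
  H <- nrow(image); W <- ncol(image)
  if (params$method == "otsu") {
    v <- pmax(image[, , 1], image[, , 2], image[, , 3])
    fg <- v > otsu_threshold(v)
  } else {
    lo <- params$rgb_lo; hi <- params$rgb_hi
    fg <- image[, , 1] >= lo[1] & image[, , 1] <= hi[1] &
      image[, , 2] >= lo[2] & image[, , 2] <= hi[2] &
      image[, , 3] >= lo[3] & image[, , 3] <= hi[3]
  }
  if (!any(fg)) {
    return(detections(image_id = params$image_id, image_size = c(H, W)))
  }
  lab <- label_components(fg)
  areas <- tabulate(lab[lab > 0L])
  small <- which(areas < params$min_area)
  if (length(small)) lab[lab %in% small] <- 0L
  if (!any(lab > 0L)) {
    return(detections(image_id = params$image_id, image_size = c(H, W)))
  }
  areas <- tabulate(lab)
  med <- stats::median(areas[areas > 0])
  # split merged blobs with a watershed on the distance map
  for (id in which(areas > params$split_factor * med)) {
    comp <- lab == id
    w <- EBImage::watershed(EBImage::distmap(EBImage::Image(comp * 1)),
                            tolerance = 1)
    wm <- matrix(as.integer(w), nrow = H)
    if (max(wm) > 1L) {
      lab[comp] <- max(lab) + wm[comp]
    }
  }
  ids <- sort(unique(lab[lab > 0L]))
  px <- which(lab > 0L, arr.ind = TRUE)
  grp <- lab[lab > 0L]
  rows <- split(px[, 1], grp)[as.character(ids)]
  cols <- split(px[, 2], grp)[as.character(ids)]
  boxes <- purrr::map2_dfr(rows, cols, function(r, c) {
    hull_area <- pixel_hull_area(r, c)
    sol <- if (hull_area > 0) length(r) / hull_area else 1
    tibble::tibble(
      x_min = min(c) - 1, y_min = min(r) - 1, x_max = max(c), y_max = max(r),
      confidence = clamp(sol, 0, 1)
    )
  })
  boxes <- boxes[boxes$x_max - boxes$x_min >= 1 & boxes$y_max - boxes$y_min >= 1, ]
  detections(boxes$x_min, boxes$y_min, boxes$x_max, boxes$y_max,
             boxes$confidence, image_id = params$image_id, image_size = c(H, W))
}

#' Baseline detector parameters
#'
#' @param method `"otsu"` thresholds the HSV value channel with Otsu's
#'   method; `"rgb_range"` keeps pixels inside a fixed per-channel RGB
#'   window (useful when grains, stem, and calibrator share brightness).
#' @param rgb_lo,rgb_hi Per-channel RGB bounds for `method = "rgb_range"`.
#' @param min_area Minimum component area (px^2) kept as a grain.
#' @param split_factor Components larger than `split_factor` x median area
#'   are watershed-split.
#' @param image_id Identifier stamped on the resulting detections.
#' @return Parameter list for [baseline_detect()].
#' @export
detect_params <- function(method = c("otsu", "rgb_range"),
                          rgb_lo = c(0.72, 0.55, 0.15),
                          rgb_hi = c(1.00, 0.90, 0.60),
                          min_area = 40, split_factor = 2.5,
                          image_id = "image") {
  list(method = match.arg(method), rgb_lo = rgb_lo, rgb_hi = rgb_hi,
       min_area = min_area, split_factor = split_factor, image_id = image_id)
}

#' Read detections from CSV or COCO-style JSON
#'
#' The CSV format is flat: `image_id,x_min,y_min,x_max,y_max,confidence`.
#' COCO-style JSON carries `images` (with `id`, `width`, `height`,
#' optionally `file_name`) and `annotations` with `bbox = [x, y, w, h]`,
#' converted here to half-open corners; an annotation `score` becomes the
#' confidence (1 when absent).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, or `"coco"`.
#' @return Detection tibble.
#' @export
read_detections <- function(path, format = c("auto", "csv", "coco")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "coco" else "csv"
  }
  if (format == "csv") {
    d <- readr::read_csv(path, col_types = readr::cols(
      image_id = readr::col_character(), x_min = readr::col_double(),
      y_min = readr::col_double(), x_max = readr::col_double(),
      y_max = readr::col_double(), confidence = readr::col_double()
    ))
    bad <- which(d$x_max <= d$x_min | d$y_max <= d$y_min)
    if (length(bad)) {
      stopf("parse error in %s line %d: box max <= min", path, bad[1] + 1L)
    }
    validate_detections(d)
    return(tibble::as_tibble(d))
  }
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(j$annotations)) stopf("parse error in %s: no 'annotations' field", path)
  ann <- j$annotations
  bb <- ann$bbox
  if (is.list(bb)) bb <- do.call(rbind, bb)
  if (is.null(dim(bb)) || ncol(bb) != 4L) {
    stopf("parse error in %s: field 'bbox' must have 4 elements", path)
  }
  ids <- as.character(ann$image_id)
  if (!is.null(j$images) && !is.null(j$images$file_name)) {
    ids <- j$images$file_name[match(ann$image_id, j$images$id)]
  }
  conf <- if (!is.null(ann$score)) ann$score else rep(1, nrow(bb))
  d <- detections(bb[, 1], bb[, 2], bb[, 1] + bb[, 3], bb[, 2] + bb[, 4],
                  conf, image_id = ids)
  d
}

#' Write detections to a flat CSV
#'
#' @param d Detection tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(d, path) {
  validate_detections(d)
  readr::write_csv(d[, c("image_id", "x_min", "y_min", "x_max", "y_max", "confidence")],
                   path)
  invisible(path)
}
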