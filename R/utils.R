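# Internal helpers shared across modules. Image convention throughout the
# package: a numeric array img[row, col, channel] with values in [0, 1];
# binary masks are logical matrices mask[row, col]. Public pixel coordinates
# are 0-based (row, col); boxes are half-open [min, max) in 0-based pixels,
# so a box's width is x_max - x_min.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# half-up rounding to the nearest integer (R's round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

as_image_array <- function(image) {
  if (is.array(image) && length(dim(image)) == 3L && dim(image)[3] >= 3L) {
    return(image[, , 1:3, drop = FALSE])
  }
  stopf("expected an RGB image array [row, col, channel]")
}

#' Read an RGB image
#'
#' Reads a PNG or JPEG file into the package's image convention: a numeric
#' array `img[row, col, channel]` with values in `[0, 1]`.
#'
#' @param path Path to a PNG or JPEG file.
#' @return Numeric array with dimensions height x width x 3.
#' @export
read_panicle_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
    return(img[, , 1:3, drop = FALSE])
  }
  x <- EBImage::readImage(path)
  a <- as.array(x)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  # EBImage stores x (col) as the first dimension
  aperm(a[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
}

#' Write an RGB image as PNG
#'
#' @param image Numeric array `[row, col, channel]` in `[0, 1]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_panicle_image <- function(image, path) {
  png::writePNG(clamp(as_image_array(image), 0, 1), path)
  invisible(path)
}

# HSV channels of an image array; h in [0, 360), s and v in [0, 1]
image_hsv <- function(image) {
  image <- as_image_array(image)
  d <- dim(image)
  rgbm <- rbind(
    as.vector(image[, , 1]),
    as.vector(image[, , 2]),
    as.vector(image[, , 3])
  )
  hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 1)
  list(
    h = matrix(hsv[1, ] * 360, d[1], d[2]),
    s = matrix(hsv[2, ], d[1], d[2]),
    v = matrix(hsv[3, ], d[1], d[2])
  )
}

# connected-component labeling of a logical mask (EBImage, 4-connected)
label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  matrix(as.integer(lab), nrow = nrow(mask))
}

# Otsu threshold of a numeric matrix in [0, 1]
otsu_threshold <- function(gray) {
  EBImage::otsu(EBImage::Image(clamp(gray, 0, 1)), range = c(0, 1), levels = 256L)
}

# area (in unit squares) of the convex hull of the corner points of the
# foreground pixels; >= number of pixels, used for solidity confidences
pixel_hull_area <- function(rows, cols) {
  x <- c(cols - 1, cols, cols - 1, cols)
  y <- c(rows - 1, rows - 1, rows, rows)
  h <- grDevices::chull(x, y)
  xs <- x[h]; ys <- y[h]
  n <- length(h)
  if (n < 3L) return(0)
  abs(sum(xs * ys[c(2:n, 1)] - xs[c(2:n, 1)] * ys)) / 2
}
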