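# Occlusion-calibrated grain counting. Grains in an intact panicle occlude
# each other, so a detector's raw count systematically undershoots. The
# panicle morphology index (PMI) quantifies that occlusion on [0, 1]
# (1 = no occlusion) and the calibrated count divides the raw count by it.

#' PMI from actual and forecast grain counts
#'
#' The panicle morphology index is defined from a panicle's true grain
#' count and a detector's forecast as
#' `PMI = 1 - |n_actual - n_forecast| / n_actual`, clamped to `[0, 1]`
#' (the unclamped expression goes negative once the forecast exceeds twice
#' the actual count, but the index is defined on `[0, 1]`). A value near 1
#' means the detector saw almost every grain (little occlusion); values
#' near 0 mean severe mutual occlusion.
#'
#' @param n_actual True grain count(s), integer >= 1.
#' @param n_forecast Detector count(s), integer >= 0. Vectorized.
#' @return Numeric vector of PMI values in `[0, 1]`.
#' @examples
#' pmi_from_counts(200, 150)  # 0.75
#' @export
pmi_from_counts <- function(n_actual, n_forecast) {
  if (any(n_actual < 1)) stopf("n_actual must be >= 1")
  if (any(n_forecast < 0)) stopf("n_forecast must be >= 0")
  clamp(1 - abs(n_actual - n_forecast) / n_actual, 0, 1)
}

#' Calibrate a raw grain count with a PMI value
#'
#' The final grain count is the raw detector count divided by the PMI,
#' rounded half-up to the nearest integer: `n_grain = round(n_predict /
#' max(pmi, pmi_floor))`. The floor guards the division as PMI approaches
#' 0, where the calibration is undefined.
#'
#' When the detector only misses grains (never double-counts) and the PMI
#' comes from the true counts, the calibration is exact:
#' PMI = n_forecast / n_actual, so n_forecast / PMI = n_actual.
#'
#' @param n_predict Raw detector count(s), >= 0. Vectorized.
#' @param pmi PMI value(s) in `[0, 1]`.
#' @param pmi_floor Smallest divisor used (> 0, default 0.05).
#' @return Tibble with columns `n_predict`, `pmi`, `n_grain` (integer).
#' @examples
#' calibrate_count(150, 0.75)$n_grain  # 200
#' @export
calibrate_count <- function(n_predict, pmi, pmi_floor = 0.05) {
  if (pmi_floor <= 0) stopf("pmi_floor must be > 0")
  if (any(n_predict < 0)) stopf("n_predict must be >= 0")
  if (any(pmi < 0 | pmi > 1)) stopf("pmi must lie in [0, 1]")
  tibble::tibble(
    n_predict = n_predict,
    pmi = pmi,
    n_grain = as.integer(round_half_up(n_predict / pmax(pmi, pmi_floor)))
  )
}

#' Heuristic PMI from detection-box overlap
#'
#' A desk-scale stand-in for an image-trained PMI model: the occluded
#' fraction is estimated from the detection boxes as
#' `(sum of box areas - area of their union) / sum of box areas`, and the
#' PMI is one minus that, clamped to `[0, 1]`. Disjoint boxes give 1; two
#' identical boxes give 0.5.
#'
#' @param d Detection tibble.
#' @param panicle_mask Accepted for interface compatibility; the value is
#'   defined purely from the boxes and the mask is ignored.
#' @return Single PMI value in `[0, 1]`.
#' @export
pmi_heuristic <- function(d, panicle_mask = NULL) {
  if (nrow(d) == 0L) {
    warning("empty detections: returning PMI 1.0", call. = FALSE)
    return(1.0)
  }
  total <- sum((d$x_max - d$x_min) * (d$y_max - d$y_min))
  un <- box_union_area(d)
  clamp(1 - (total - un) / total, 0, 1)
}

# exact union area of axis-aligned boxes via coordinate compression
box_union_area <- function(d) {
  xs <- sort(unique(c(d$x_min, d$x_max)))
  ys <- sort(unique(c(d$y_min, d$y_max)))
  nx <- length(xs) - 1L; ny <- length(ys) - 1L
  covered <- matrix(FALSE, ny, nx)
  for (i in seq_len(nrow(d))) {
    cx <- which(xs >= d$x_min[i] & xs < d$x_max[i])
    cy <- which(ys >= d$y_min[i] & ys < d$y_max[i])
    covered[cy, cx] <- TRUE
  }
  cw <- diff(xs); ch <- diff(ys)
  sum(outer(ch, cw)[covered])
}

#' PMI provider contract
#'
#' Returns a function `image_id -> PMI` so the pipeline can consume PMI
#' values from any source: `"ground_truth"` computes them from a table of
#' true/forecast count pairs (columns `image_id`, `n_actual`,
#' `n_forecast`); `"external"` reads per-image values produced by any
#' model from a CSV (columns `image_id`, `pmi`) or an equivalent data
#' frame.
#'
#' @param kind `"ground_truth"` or `"external"`.
#' @param source Data frame or CSV path as described above.
#' @return Function of one argument `image_id` returning a PMI in `[0, 1]`;
#'   querying an id absent from the source is an error.
#' @export
pmi_provider <- function(kind = c("ground_truth", "external"), source) {
  kind <- match.arg(kind)
  tab <- if (is.character(source)) {
    readr::read_csv(source, col_types = readr::cols(image_id = readr::col_character()))
  } else {
    tibble::as_tibble(source)
  }
  if (kind == "ground_truth") {
    stopifnot(all(c("image_id", "n_actual", "n_forecast") %in% names(tab)))
    vals <- stats::setNames(pmi_from_counts(tab$n_actual, tab$n_forecast),
                            tab$image_id)
  } else {
    stopifnot(all(c("image_id", "pmi") %in% names(tab)))
    if (any(tab$pmi < 0 | tab$pmi > 1)) stopf("external PMI outside [0, 1]")
    vals <- stats::setNames(tab$pmi, tab$image_id)
  }
  function(image_id) {
    if (!image_id %in% names(vals)) {
      stopf("no PMI available for image_id '%s'", image_id)
    }
    unname(vals[[image_id]])
  }
}
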