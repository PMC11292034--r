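# Ground-truthed synthetic panicle scenes. A scene emulates the acquisition
# protocol: a uniform background board, a red calibrator disk of known pixel
# and physical radius, a curved stem with short side branches, and elliptical
# grains at a controllable mutual-overlap level. Every drawn element is
# recorded in a truth table so each pipeline stage can be verified exactly.

#' Specification of a synthetic panicle scene
#'
#' The defaults are the package's study conditions, a desk-scale emulation
#' of 3000x4000 smartphone captures: 1000x1400 px, calibrator radius
#' 200 px / 25 mm (0.125 mm per pixel, so a 9 mm grain is 72 px long), 30
#' grains of 9.0 +/- 0.5 mm by 3.0 +/- 0.2 mm, tan grains and a green stem
#' on a gray board.
#'
#' @param image_size `(H, W)` in pixels.
#' @param calibrator List: `center` `(row, col)`, `pixel_radius`,
#'   `real_radius_mm`.
#' @param stem List: `include`, `thickness` (px), `amplitude` (px, lateral
#'   sine sweep of the centerline), `periods`, `col_frac` (horizontal
#'   position as a fraction of W), `row_range` (top/bottom as fractions of
#'   H), `n_branches`, `branch_thickness`.
#' @param n_grains Number of grains (may be 0).
#' @param grain_length_mm,grain_width_mm `c(mean, sd)` in mm.
#' @param overlap_level Target mutual-overlap level in `[0, 1]`: the
#'   probability that a grain is placed overlapping an earlier grain, with
#'   center distance shrinking as the level rises; 0 guarantees pairwise
#'   disjoint boxes.
#' @param placement `"region"` scatters grains in `grain_region`
#'   (occlusion controlled by `overlap_level`); `"branches"` anchors each
#'   grain on the branch/upper-stem network so the panicle is one
#'   connected object, as in real photographs (crowding then arises
#'   naturally; `overlap_level = 0` still enforces disjoint boxes).
#' @param grain_region Placement window as fractions of `(rows, cols)`;
#'   the default keeps grains clear of the stem corridor and calibrator.
#' @param colors Named list of RGB triples: `board`, `calibrator`, `stem`,
#'   `grain`.
#' @param noise_sd Gaussian pixel noise sd.
#' @param seed Scene seed (integer).
#' @param image_id Identifier; default `"scene_<seed>"`.
#' @param max_attempts Placement attempts per grain before failing.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_size = c(1000, 1400),
                       calibrator = list(center = c(220, 220),
                                         pixel_radius = 200,
                                         real_radius_mm = 25),
                       stem = list(include = TRUE, thickness = 5,
                                   amplitude = 40, periods = 1,
                                   col_frac = 0.38, row_range = c(0.06, 0.95),
                                   n_branches = 6, branch_thickness = 3),
                       n_grains = 30,
                       grain_length_mm = c(mean = 9.0, sd = 0.5),
                       grain_width_mm = c(mean = 3.0, sd = 0.2),
                       overlap_level = 0,
                       placement = c("region", "branches"),
                       grain_region = list(rows = c(0.04, 0.96),
                                           cols = c(0.46, 0.97)),
                       colors = list(board = c(0.72, 0.72, 0.72),
                                     calibrator = c(0.85, 0.08, 0.08),
                                     stem = c(0.20, 0.55, 0.15),
                                     grain = c(0.85, 0.72, 0.35)),
                       noise_sd = 0.01,
                       seed = 1L,
                       image_id = NULL,
                       max_attempts = 2000L) {
  stopifnot(all(image_size > 0), calibrator$pixel_radius > 0,
            overlap_level >= 0, overlap_level <= 1, n_grains >= 0)
  placement <- match.arg(placement)
  if (placement == "branches" && !isTRUE(stem$include)) {
    stopf("placement = 'branches' requires stem$include = TRUE")
  }
  structure(
    list(image_size = image_size, calibrator = calibrator, stem = stem,
         n_grains = n_grains, grain_length_mm = grain_length_mm,
         grain_width_mm = grain_width_mm, overlap_level = overlap_level,
         placement = placement,
         grain_region = grain_region, colors = colors, noise_sd = noise_sd,
         seed = as.integer(seed),
         image_id = image_id %||% paste0("scene_", seed),
         max_attempts = max_attempts),
    class = "scene_spec"
  )
}

#' Rescale the pixel quantities of a scene spec
#'
#' Multiplies image size, calibrator geometry, stem thickness/amplitude and
#' noise-free pixel geometry by `k`; physical (mm) quantities are
#' untouched, so the implied mm-per-pixel divides by `k`. Used for
#' scale-invariance checks.
#'
#' @param spec A `scene_spec`.
#' @param k Scale factor (> 0).
#' @return A rescaled `scene_spec`.
#' @export
scale_scene_spec <- function(spec, k) {
  stopifnot(inherits(spec, "scene_spec"), k > 0)
  spec$image_size <- round(spec$image_size * k)
  spec$calibrator$center <- spec$calibrator$center * k
  spec$calibrator$pixel_radius <- spec$calibrator$pixel_radius * k
  spec$stem$thickness <- max(1, round(spec$stem$thickness * k))
  spec$stem$amplitude <- spec$stem$amplitude * k
  spec$stem$branch_thickness <- max(1, round(spec$stem$branch_thickness * k))
  spec$image_id <- paste0(spec$image_id, "_x", k)
  spec
}

#' Scene preset for panicle-length studies
#'
#' A grain-free curved stem with many short side branches, at a coarser
#' scale (0.625 mm/px) where the whole stem fits in frame and the
#' branched stem out-areas the calibrator disk — the area ordering of
#' real photographs, where the dense panicle is always the largest
#' colored object.
#'
#' @param seed Scene seed.
#' @param ... Overrides passed to [scene_spec()].
#' @return A `scene_spec`.
#' @export
panicle_scene_spec <- function(seed = 1L, ...) {
  scene_spec(
    image_size = c(700, 600),
    calibrator = list(center = c(70, 70), pixel_radius = 40, real_radius_mm = 25),
    stem = list(include = TRUE, thickness = 9, amplitude = 30, periods = 1,
                col_frac = 0.55, row_range = c(0.06, 0.95),
                n_branches = 10, branch_thickness = 5),
    n_grains = 0,
    seed = seed,
    ...
  )
}

#' Scene preset for the full end-to-end pipeline
#'
#' A connected panicle: grains are anchored on the branch/upper-stem
#' network (`placement = "branches"`), so calibration, grain counting,
#' morphometry, and panicle length all run on the same image. 150 grains
#' at 0.352 mm/px make the panicle the largest colored component.
#'
#' @param seed Scene seed.
#' @param ... Overrides passed to [scene_spec()].
#' @return A `scene_spec`.
#' @export
pipeline_scene_spec <- function(seed = 1L, ...) {
  scene_spec(
    image_size = c(800, 600),
    calibrator = list(center = c(85, 85), pixel_radius = 71, real_radius_mm = 25),
    stem = list(include = TRUE, thickness = 8, amplitude = 25, periods = 1,
                col_frac = 0.55, row_range = c(0.06, 0.95),
                n_branches = 10, branch_thickness = 4),
    n_grains = 150,
    overlap_level = 0.5,
    placement = "branches",
    seed = seed,
    ...
  )
}

# deterministic substream seed for scene i of a batch
scene_substream <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483629)
}

# axis-aligned half-extents of a rotated ellipse with semi-axes a, b at
# angle theta (degrees, from the column axis)
ellipse_extents <- function(a, b, theta_deg) {
  th <- theta_deg * pi / 180
  c(wx = sqrt((a * cos(th))^2 + (b * sin(th))^2),
    wy = sqrt((a * sin(th))^2 + (b * cos(th))^2))
}

# stamp a soft-edged ellipse into an image window (in place, returns image)
draw_ellipse <- function(img, cr, cc, a, b, theta_deg, color) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ext <- ellipse_extents(a, b, theta_deg)
  r0 <- max(1, floor(cr - ext["wy"])); r1 <- min(H, ceiling(cr + ext["wy"]) + 1)
  c0 <- max(1, floor(cc - ext["wx"])); c1 <- min(W, ceiling(cc + ext["wx"]) + 1)
  rr <- r0:r1; ccn <- c0:c1
  # pixel centers in 0-based continuous coords
  py <- matrix(rr - 0.5, length(rr), length(ccn)) - cr
  px <- matrix(rep(ccn - 0.5, each = length(rr)), length(rr), length(ccn)) - cc
  th <- theta_deg * pi / 180
  u <- px * cos(th) + py * sin(th)
  v <- -px * sin(th) + py * cos(th)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  phi <- atan2(v, u)
  rdir <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  alpha <- clamp((1 - rho) * rdir + 0.5, 0, 1)   # anti-aliased coverage
  for (ch in 1:3) {
    img[rr, ccn, ch] <- img[rr, ccn, ch] * (1 - alpha) + color[ch] * alpha
  }
  img
}

# stamp disks of a given radius at sample points; returns a logical mask
stamp_disks <- function(H, W, rows, cols, radius) {
  rad <- ceiling(radius)
  off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  off <- off[off$dr^2 + off$dc^2 <= radius^2 + 1e-9, ]
  pr <- round(rows); pc <- round(cols)
  allr <- rep(pr, each = nrow(off)) + off$dr
  allc <- rep(pc, each = nrow(off)) + off$dc
  ok <- allr >= 1 & allr <= H & allc >= 1 & allc <= W
  mask <- matrix(FALSE, H, W)
  mask[cbind(allr[ok], allc[ok])] <- TRUE
  mask
}

# the stem centerline as dense 1-based continuous sample points
stem_centerline <- function(spec, amplitude, phase, n = 4000) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  t <- seq(0, 1, length.out = n)
  row <- H * (spec$stem$row_range[2] + t * (spec$stem$row_range[1] - spec$stem$row_range[2]))
  col <- W * spec$stem$col_frac + amplitude * sin(2 * pi * spec$stem$periods * t + phase)
  cbind(row = row, col = col)
}

#' Generate a synthetic panicle scene
#'
#' Deterministic given `spec$seed`: the same spec renders bit-identical
#' images. With `render = FALSE` only the ground truth (grain geometry,
#' stem skeleton statistics, calibrator) is produced, which is much faster
#' for count-level simulation studies.
#'
#' @param spec A [scene_spec()].
#' @param render Draw the RGB image (default `TRUE`).
#' @return List with `image` (RGB array, or `NULL` when `render = FALSE`)
#'   and `truth` (see Details). `truth$grains` is a tibble with the drawn
#'   ellipse (0-based center, semi-axes in px, angle) and its axis-aligned
#'   half-open box; `truth$stem` records the centerline arc length and the
#'   rasterized centerline (skeleton) pixel count; `truth$mm_per_pixel`
#'   is implied by the calibrator.
#' @export
generate_scene <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  mm_per_px <- spec$calibrator$real_radius_mm / spec$calibrator$pixel_radius

  # stem geometry (drawn later, but sampled first so the RNG stream is
  # stable whether or not rendering happens)
  amplitude <- spec$stem$amplitude * stats::runif(1, 0.8, 1.2)
  phase <- stats::runif(1, 0, 2 * pi)
  stem_truth <- NULL
  branches <- list()
  if (isTRUE(spec$stem$include)) {
    cl <- stem_centerline(spec, amplitude, phase)
    arc_px <- sum(sqrt(diff(cl[, 1])^2 + diff(cl[, 2])^2))
    # pixel count of the ideal 8-connected digital centerline: one pixel
    # per unit of Chebyshev arc length (diagonal steps advance both axes)
    cheb_px <- round(1 + sum(pmax(abs(diff(cl[, 1])), abs(diff(cl[, 2])))))
    stem_truth <- list(arc_px = arc_px, skeleton_px = cheb_px,
                       bottom = cl[1, ] - 1, top = cl[nrow(cl), ] - 1)
    nb <- spec$stem$n_branches
    if (nb > 0) {
      tpos <- seq(0.2, 0.75, length.out = nb)
      for (j in seq_len(nb)) {
        t0 <- tpos[j]
        idx <- max(1, round(t0 * nrow(cl)))
        p0 <- cl[idx, ]
        side <- if (j %% 2 == 0) 1 else -1
        ang <- stats::runif(1, 35, 60) * pi / 180
        len <- min(stats::runif(1, 0.04, 0.08) * H, 0.45 * (1 - t0) * arc_px)
        tt <- seq(0, 1, length.out = 200)
        branches[[j]] <- cbind(row = p0[1] - tt * len * sin(ang),
                               col = p0[2] + side * tt * len * cos(ang))
      }
    }
  }

  # grain geometry and placement
  grains <- placement_boxes <- NULL
  if (spec$n_grains > 0) {
    lens <- pmax(stats::rnorm(spec$n_grains, spec$grain_length_mm[["mean"]],
                              spec$grain_length_mm[["sd"]]), 2)
    wids <- pmax(stats::rnorm(spec$n_grains, spec$grain_width_mm[["mean"]],
                              spec$grain_width_mm[["sd"]]), 0.8)
    lens <- pmax(lens, wids + 0.5)
    a <- lens / mm_per_px / 2
    b <- wids / mm_per_px / 2
    angle <- stats::runif(spec$n_grains, 0, 180)
    rmin <- H * spec$grain_region$rows[1]; rmax <- H * spec$grain_region$rows[2]
    cmin <- W * spec$grain_region$cols[1]; cmax <- W * spec$grain_region$cols[2]
    anchors <- NULL
    if (spec$placement == "branches") {
      anchors <- do.call(rbind, branches)
      upper <- cl[cl[, 1] <= stats::quantile(cl[, 1], 0.45), , drop = FALSE]
      anchors <- rbind(anchors, upper)
    }
    cal_box <- tibble::tibble(
      x_min = spec$calibrator$center[2] - spec$calibrator$pixel_radius - 4,
      y_min = spec$calibrator$center[1] - spec$calibrator$pixel_radius - 4,
      x_max = spec$calibrator$center[2] + spec$calibrator$pixel_radius + 4,
      y_max = spec$calibrator$center[1] + spec$calibrator$pixel_radius + 4
    )
    boxes <- tibble::tibble(x_min = numeric(), y_min = numeric(),
                            x_max = numeric(), y_max = numeric())
    centers <- matrix(numeric(), 0, 2)
    for (i in seq_len(spec$n_grains)) {
      ext <- ellipse_extents(a[i], b[i], angle[i])
      placed <- FALSE
      for (att in seq_len(spec$max_attempts)) {
        overlap_mode <- FALSE
        if (spec$placement == "branches") {
          anc <- anchors[sample.int(nrow(anchors), 1), ]
          cr <- anc[1] + stats::rnorm(1, 0, 3)
          cc <- anc[2] + stats::rnorm(1, 0, 3)
        } else {
          overlap_mode <- nrow(boxes) > 0 && stats::runif(1) < spec$overlap_level
          if (overlap_mode) {
            base <- sample.int(nrow(boxes), 1)
            dist <- (1.2 - spec$overlap_level) * a[i]
            dir <- stats::runif(1, 0, 2 * pi)
            cr <- centers[base, 1] + dist * sin(dir)
            cc <- centers[base, 2] + dist * cos(dir)
          } else {
            cr <- stats::runif(1, rmin + ext[["wy"]], rmax - ext[["wy"]])
            cc <- stats::runif(1, cmin + ext[["wx"]], cmax - ext[["wx"]])
          }
        }
        if (cr - ext[["wy"]] < 1 || cr + ext[["wy"]] > H - 1 ||
            cc - ext[["wx"]] < 1 || cc + ext[["wx"]] > W - 1) next
        box <- tibble::tibble(x_min = floor(cc - ext[["wx"]]),
                              y_min = floor(cr - ext[["wy"]]),
                              x_max = ceiling(cc + ext[["wx"]]),
                              y_max = ceiling(cr + ext[["wy"]]))
        if (box_iou(box, cal_box) > 0) next
        if (nrow(boxes) > 0) {
          ious <- box_iou(boxes, box[rep(1, nrow(boxes)), ])
          if (spec$placement == "branches") {
            if (spec$overlap_level == 0 && max(ious) > 0) next
          } else if (overlap_mode) {
            if (max(ious) == 0) next        # must actually overlap its base
          } else if (max(ious) > 0) next    # must stay disjoint
        }
        boxes <- dplyr::bind_rows(boxes, box)
        centers <- rbind(centers, c(cr, cc))
        placed <- TRUE
        break
      }
      if (!placed) {
        stopf("placement error: could not place grain %d at overlap level %.2f",
              i, spec$overlap_level)
      }
    }
    grains <- tibble::tibble(
      grain = seq_len(spec$n_grains),
      center_row = centers[, 1] - 0.5,   # 0-based pixel-center coordinates
      center_col = centers[, 2] - 0.5,
      a_px = a, b_px = b, angle_deg = angle,
      length_mm = lens, width_mm = wids,
      x_min = boxes$x_min, y_min = boxes$y_min,
      x_max = boxes$x_max, y_max = boxes$y_max
    )
  } else {
    grains <- tibble::tibble(
      grain = integer(), center_row = numeric(), center_col = numeric(),
      a_px = numeric(), b_px = numeric(), angle_deg = numeric(),
      length_mm = numeric(), width_mm = numeric(),
      x_min = numeric(), y_min = numeric(), x_max = numeric(), y_max = numeric()
    )
  }

  truth <- list(
    image_id = spec$image_id,
    image_size = c(H, W),
    mm_per_pixel = mm_per_px,
    calibrator = list(center = spec$calibrator$center - 0.5,
                      pixel_radius = spec$calibrator$pixel_radius,
                      real_radius_mm = spec$calibrator$real_radius_mm),
    grains = grains,
    n_grains = spec$n_grains,
    stem = stem_truth,
    overlap_level = spec$overlap_level,
    seed = spec$seed
  )

  image <- NULL
  if (render) {
    image <- array(0, dim = c(H, W, 3))
    noise <- matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
    for (ch in 1:3) image[, , ch] <- spec$colors$board[ch] + noise
    # calibrator disk, anti-aliased
    ctr <- spec$calibrator$center; R <- spec$calibrator$pixel_radius
    r0 <- max(1, floor(ctr[1] - R - 1)); r1 <- min(H, ceiling(ctr[1] + R + 1))
    c0 <- max(1, floor(ctr[2] - R - 1)); c1 <- min(W, ceiling(ctr[2] + R + 1))
    rr <- r0:r1; ccn <- c0:c1
    dy <- matrix(rr - 0.5, length(rr), length(ccn)) - (ctr[1] - 0.5)
    dx <- matrix(rep(ccn - 0.5, each = length(rr)), length(rr), length(ccn)) - (ctr[2] - 0.5)
    alpha <- clamp(R + 0.5 - sqrt(dx^2 + dy^2), 0, 1)
    for (ch in 1:3) {
      image[rr, ccn, ch] <- image[rr, ccn, ch] * (1 - alpha) +
        spec$colors$calibrator[ch] * alpha
    }
    # stem and branches
    if (isTRUE(spec$stem$include)) {
      cl <- stem_centerline(spec, amplitude, phase)
      smask <- stamp_disks(H, W, cl[, 1], cl[, 2], spec$stem$thickness / 2)
      for (br in branches) {
        smask <- smask | stamp_disks(H, W, br[, 1], br[, 2],
                                     spec$stem$branch_thickness / 2)
      }
      for (ch in 1:3) {
        chan <- image[, , ch]
        chan[smask] <- spec$colors$stem[ch]
        image[, , ch] <- chan
      }
    }
    if (spec$n_grains > 0) {
      for (i in seq_len(spec$n_grains)) {
        image <- draw_ellipse(image, grains$center_row[i] + 0.5,
                              grains$center_col[i] + 0.5,
                              grains$a_px[i], grains$b_px[i],
                              grains$angle_deg[i], spec$colors$grain)
      }
    }
    image <- clamp(image, 0, 1)
  }
  list(image = image, truth = truth)
}

#' Ground-truth boxes of a scene as a detection tibble
#'
#' @param truth The `truth` element of [generate_scene()].
#' @param confidence Confidence assigned to every truth box (default 1).
#' @return Detection tibble.
#' @export
truth_boxes <- function(truth, confidence = 1) {
  g <- truth$grains
  detections(g$x_min, g$y_min, g$x_max, g$y_max, confidence,
             image_id = truth$image_id, image_size = truth$image_size)
}

#' Detector error model for simulated detections
#'
#' Each grain is detected with probability `1 - alpha * o`, where `o` is
#' the grain's maximum box IoU with any other grain (its occlusion).
#' Detected boxes are jittered and given confidences
#' `clamp(conf_base - conf_slope * o + N(0, conf_sd), 0.01, 0.999)`.
#'
#' @param alpha Occlusion sensitivity of the miss probability in `[0, 1]`.
#' @param jitter_sd Gaussian sd (px) added to each box edge.
#' @param conf_base,conf_slope,conf_sd Confidence model parameters.
#' @param fp_rate Expected number of spurious boxes per scene (Poisson).
#' @return An error-model list.
#' @export
detector_error_model <- function(alpha = 1, jitter_sd = 1,
                                 conf_base = 0.9, conf_slope = 0.3,
                                 conf_sd = 0.05, fp_rate = 0) {
  stopifnot(alpha >= 0, alpha <= 1, jitter_sd >= 0, fp_rate >= 0)
  list(alpha = alpha, jitter_sd = jitter_sd, conf_base = conf_base,
       conf_slope = conf_slope, conf_sd = conf_sd, fp_rate = fp_rate)
}

# per-grain occlusion: max box IoU with any other grain
grain_occlusion <- function(truth) {
  d <- truth_boxes(truth)
  n <- nrow(d)
  if (n <= 1L) return(rep(0, n))
  M <- iou_matrix(d)
  diag(M) <- 0
  apply(M, 1, max)
}

#' Simulate detector output for a scene truth
#'
#' Applies the [detector_error_model()] to the ground-truth boxes:
#' occlusion-dependent misses, box jitter, sampled confidences, optional
#' false positives. Deterministic given `seed`.
#'
#' @param truth Scene truth from [generate_scene()].
#' @param error_model A [detector_error_model()].
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return Detection tibble.
#' @export
simulate_detections <- function(truth, error_model = detector_error_model(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- truth$grains
  H <- truth$image_size[1]; W <- truth$image_size[2]
  if (nrow(g) == 0L) {
    return(detections(image_id = truth$image_id, image_size = truth$image_size))
  }
  o <- grain_occlusion(truth)
  detected <- stats::runif(nrow(g)) >= error_model$alpha * o
  d <- g[detected, , drop = FALSE]
  od <- o[detected]
  n <- nrow(d)
  jit <- function(x) x + stats::rnorm(length(x), 0, error_model$jitter_sd)
  x_min <- jit(d$x_min); y_min <- jit(d$y_min)
  x_max <- pmax(jit(d$x_max), x_min + 2)
  y_max <- pmax(jit(d$y_max), y_min + 2)
  conf <- clamp(error_model$conf_base - error_model$conf_slope * od +
                  stats::rnorm(n, 0, error_model$conf_sd), 0.01, 0.999)
  out <- detections(x_min, y_min, x_max, y_max, conf,
                    image_id = truth$image_id)
  if (error_model$fp_rate > 0) {
    nfp <- stats::rpois(1, error_model$fp_rate)
    if (nfp > 0) {
      wl <- mean(d$x_max - d$x_min); hl <- mean(d$y_max - d$y_min)
      fx <- stats::runif(nfp, 0, W - wl); fy <- stats::runif(nfp, 0, H - hl)
      fp <- detections(fx, fy, fx + wl, fy + hl,
                       stats::runif(nfp, 0.3, 0.7), image_id = truth$image_id)
      out <- dplyr::bind_rows(out, fp)
    }
  }
  clip_detections(out, truth$image_size)
}

#' Build a PMI dataset from a batch of scene specs
#'
#' For every spec, places the grains (no rendering), simulates a detector
#' under the error model, and records the actual count, the forecast
#' count, and the PMI computed from the two counts. Scene `i` uses a
#' deterministic substream of `seed`, so it is reproducible independently
#' of the batch size.
#'
#' @param specs List of [scene_spec()]s (seeds are overridden by the
#'   batch substreams).
#' @param error_model A [detector_error_model()].
#' @param seed Batch seed.
#' @return Tibble with `image_id`, `n_actual`, `n_forecast`, `pmi`.
#' @export
pmi_dataset <- function(specs, error_model = detector_error_model(), seed = 1L) {
  purrr::map_dfr(seq_along(specs), function(i) {
    sp <- specs[[i]]
    sp$seed <- scene_substream(seed, 2L * i)
    sc <- generate_scene(sp, render = FALSE)
    det <- simulate_detections(sc$truth, error_model,
                               seed = scene_substream(seed, 2L * i + 1L))
    n_actual <- sc$truth$n_grains
    n_forecast <- nrow(det)
    tibble::tibble(
      image_id = sc$truth$image_id,
      n_actual = n_actual,
      n_forecast = n_forecast,
      pmi = pmi_from_counts(n_actual, n_forecast)
    )
  })
}

#' Write a scene to disk
#'
#' Writes `<image_id>.png` and a `<image_id>_truth.json` (grain table,
#' calibrator, stem statistics) into `dir`.
#'
#' @param scene A list from [generate_scene()] (rendered).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_scene <- function(scene, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- scene$truth$image_id
  png_path <- file.path(dir, paste0(id, ".png"))
  json_path <- file.path(dir, paste0(id, "_truth.json"))
  if (is.null(scene$image)) stopf("scene was generated with render = FALSE")
  write_panicle_image(scene$image, png_path)
  jsonlite::write_json(scene$truth, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(image = png_path, truth = json_path))
}
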