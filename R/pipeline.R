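# Batch pipeline: calibrate -> detect (or load detections) -> count with
# PMI -> grain morphometry -> panicle length, one tidy row per image.
# Per-image failures are recorded in the row's `reason` and never abort
# the batch.

#' Pipeline configuration
#'
#' @param detector `"baseline"` to run [baseline_detect()], or
#'   `"detections-file"` to read boxes from `detections_path`.
#' @param detect_params Parameters for the baseline detector
#'   ([detect_params()]).
#' @param detections_path CSV/COCO file of externally supplied detections
#'   (required when `detector = "detections-file"`).
#' @param screening A [screening_config()].
#' @param pmi `"heuristic"` to estimate PMI from detection-box overlap, or
#'   a provider function from [pmi_provider()].
#' @param pmi_floor Divisor floor for [calibrate_count()].
#' @param real_radius_mm Physical calibrator radius.
#' @param calibrator_color HSV bounds for [detect_calibrator()].
#' @param segment_method,seg_rgb_lo,seg_rgb_hi Grain segmentation options
#'   for [measure_grains()].
#' @param s_threshold,min_area,n_candidates,length_mode Panicle-length
#'   options (see [measure_panicle_length()]).
#' @param seed Integer seed applied before each image for any stochastic
#'   step, keeping reruns byte-identical.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(detector = c("baseline", "detections-file"),
                            detect_params = panicletraits::detect_params(),
                            detections_path = NULL,
                            screening = screening_config(),
                            pmi = "heuristic",
                            pmi_floor = 0.05,
                            real_radius_mm = 25,
                            calibrator_color = list(hue_low = 10, hue_high = 350,
                                                    sat_min = 0.4, val_min = 0.2),
                            segment_method = "otsu",
                            seg_rgb_lo = c(0.72, 0.55, 0.15),
                            seg_rgb_hi = c(1.00, 0.90, 0.60),
                            s_threshold = "otsu",
                            min_area = NULL,
                            n_candidates = 20,
                            length_mode = "pixel_count",
                            seed = 1L) {
  detector <- match.arg(detector)
  if (detector == "detections-file" && is.null(detections_path)) {
    stopf("detections_path is required when detector = 'detections-file'")
  }
  structure(
    list(detector = detector, detect_params = detect_params,
         detections_path = detections_path, screening = screening,
         pmi = pmi, pmi_floor = pmi_floor, real_radius_mm = real_radius_mm,
         calibrator_color = calibrator_color,
         segment_method = segment_method,
         seg_rgb_lo = seg_rgb_lo, seg_rgb_hi = seg_rgb_hi,
         s_threshold = s_threshold, min_area = min_area,
         n_candidates = n_candidates, length_mode = length_mode,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# one NA-filled trait row; reasons explain missing stages
trait_row <- function(image_id) {
  tibble::tibble(
    image_id = image_id, mm_per_pixel = NA_real_,
    n_predict = NA_integer_, pmi = NA_real_, n_grain = NA_integer_,
    n_measured = NA_integer_, mean_length_mm = NA_real_,
    mean_width_mm = NA_real_, mean_aspect = NA_real_,
    panicle_length_px = NA_real_, panicle_length_mm = NA_real_,
    reason = NA_character_
  )
}

analyze_one <- function(image, image_id, config) {
  set.seed(config$seed)
  row <- trait_row(image_id)
  reasons <- character(0)
  pel <- tryCatch({
    cal <- detect_calibrator(image, config$calibrator_color)
    pel_density(cal, config$real_radius_mm)
  }, error = function(e) {
    reasons <<- c(reasons, conditionMessage(e))
    NULL
  })
  if (!is.null(pel)) row$mm_per_pixel <- pel$mm_per_pixel

  det <- tryCatch({
    if (config$detector == "baseline") {
      p <- config$detect_params
      p$image_id <- image_id
      baseline_detect(image, p)
    } else {
      d <- read_detections(config$detections_path)
      d <- d[d$image_id == image_id, , drop = FALSE]
      clip_detections(d, dim(image)[1:2])
    }
  }, error = function(e) {
    reasons <<- c(reasons, paste0("detection: ", conditionMessage(e)))
    NULL
  })

  if (!is.null(det)) {
    row$n_predict <- nrow(det)
    pmi_val <- tryCatch({
      if (is.function(config$pmi)) config$pmi(image_id) else pmi_heuristic(det)
    }, error = function(e) {
      reasons <<- c(reasons, paste0("pmi: ", conditionMessage(e)))
      NA_real_
    })
    row$pmi <- pmi_val
    if (!is.na(pmi_val)) {
      row$n_grain <- calibrate_count(nrow(det), pmi_val, config$pmi_floor)$n_grain
    }
    if (!is.null(pel)) {
      meas <- tryCatch(
        measure_grains(image, det, config$screening, pel,
                       segment_method = config$segment_method,
                       rgb_lo = config$seg_rgb_lo, rgb_hi = config$seg_rgb_hi),
        error = function(e) {
          reasons <<- c(reasons, paste0("morphometry: ", conditionMessage(e)))
          NULL
        })
      if (!is.null(meas)) {
        st <- panicle_grain_stats(meas)
        row$n_measured <- st$n_measured
        row$mean_length_mm <- st$mean_length_mm
        row$mean_width_mm <- st$mean_width_mm
        row$mean_aspect <- st$mean_aspect
      }
    }
  }

  plen <- tryCatch({
    mask <- segment_panicle(image, config$s_threshold)
    mask <- clean_mask(mask, config$min_area)
    sk <- skeletonize(mask)
    mp <- main_path(sk, config$n_candidates)
    list(px = path_px_length(mp, config$length_mode), mp = mp)
  }, error = function(e) {
    reasons <<- c(reasons, paste0("panicle length: ", conditionMessage(e)))
    NULL
  })
  if (!is.null(plen)) {
    row$panicle_length_px <- plen$px
    if (!is.null(pel)) row$panicle_length_mm <- plen$px * pel$mm_per_pixel
  }
  if (length(reasons)) row$reason <- paste(reasons, collapse = "; ")
  row
}

#' Analyze a batch of panicle images
#'
#' Runs the full trait-extraction pipeline on each image and returns one
#' tidy row per image with the calibrated grain count, PMI, mean grain
#' dimensions, panicle length, and pel density. A failure in any stage of
#' any image nulls the affected fields and is recorded in `reason`;
#' it never aborts the batch or alters another image's row.
#'
#' @param images Character vector of image paths, or a named list of RGB
#'   arrays (names become image ids).
#' @param config A [pipeline_config()].
#' @param out_csv Optional path; when given, the result is also written
#'   as CSV.
#' @return Tibble of per-image trait rows.
#' @export
analyze_panicles <- function(images, config = pipeline_config(), out_csv = NULL) {
  if (length(images) == 0L) stopf("no images to analyze")
  rows <- purrr::map(seq_along(images), function(i) {
    if (is.character(images)) {
      id <- sub("\\.[A-Za-z]+$", "", basename(images[[i]]))
      img <- tryCatch(read_panicle_image(images[[i]]), error = function(e) NULL)
      if (is.null(img)) {
        r <- trait_row(id)
        r$reason <- "unreadable image"
        return(r)
      }
    } else {
      id <- names(images)[i] %||% paste0("image_", i)
      if (id == "") id <- paste0("image_", i)
      img <- images[[i]]
    }
    analyze_one(img, id, config)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_csv)) readr::write_csv(out, out_csv)
  out
}

#' Simulate a batch of scenes to disk
#'
#' Renders `n` scenes derived from a base spec (per-scene seed
#' substreams), writes each PNG + truth JSON via [write_scene()], and a
#' batch-level CSV of the truth counts.
#'
#' @param base_spec A [scene_spec()] serving as the template.
#' @param n Number of scenes.
#' @param dir Output directory.
#' @param seed Batch seed.
#' @return Tibble (also written as `scenes.csv` in `dir`) with one row
#'   per scene: `image_id`, `n_grains`, `mm_per_pixel`, `overlap_level`.
#' @export
simulate_scenes <- function(base_spec = scene_spec(), n = 3, dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    sp <- base_spec
    sp$seed <- scene_substream(seed, i)
    sp$image_id <- sprintf("scene_%03d", i)
    sc <- generate_scene(sp, render = TRUE)
    write_scene(sc, dir)
    tibble::tibble(
      image_id = sp$image_id,
      n_grains = sc$truth$n_grains,
      mm_per_pixel = sc$truth$mm_per_pixel,
      overlap_level = sp$overlap_level
    )
  })
  readr::write_csv(rows, file.path(dir, "scenes.csv"))
  rows
}

#' Evaluate predicted traits against truth
#'
#' Joins prediction and truth tables on `image_id` (unmatched ids are
#' listed in a warning and excluded) and reports the full metric set for
#' one paired column.
#'
#' @param pred,truth Data frames (or CSV paths) containing `image_id` and
#'   the compared column.
#' @param column Name of the trait column present in both tables.
#' @return One-row [metric_report()] tibble.
#' @export
evaluate_predictions <- function(pred, truth, column) {
  if (is.character(pred)) pred <- readr::read_csv(pred, show_col_types = FALSE)
  if (is.character(truth)) truth <- readr::read_csv(truth, show_col_types = FALSE)
  stopifnot(column %in% names(pred), column %in% names(truth))
  un <- c(setdiff(pred$image_id, truth$image_id),
          setdiff(truth$image_id, pred$image_id))
  if (length(un)) {
    warning(sprintf("excluding %d unmatched image_id(s): %s", length(un),
                    paste(utils::head(un, 5), collapse = ", ")), call. = FALSE)
  }
  j <- dplyr::inner_join(
    dplyr::select(pred, "image_id", forecast = dplyr::all_of(column)),
    dplyr::select(truth, "image_id", actual = dplyr::all_of(column)),
    by = "image_id"
  )
  if (nrow(j) == 0L) stopf("no overlapping image_ids to evaluate")
  metric_report(j$actual, j$forecast)
}
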