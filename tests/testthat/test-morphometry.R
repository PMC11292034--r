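test_that("screening composes NMS, confidence filter, and overlap filter", {
  set.seed(11)
  n <- 8
  x0 <- runif(n, 0, 80); y0 <- runif(n, 0, 80)
  d <- detections(x0, y0, x0 + runif(n, 10, 30), y0 + runif(n, 10, 30),
                  round(runif(n, 0.4, 1), 3))
  cfg <- screening_config(conf = 0.6, nms_iou = 0.4)
  by_hand <- filter_confidence(nms(d, 0.4), 0.6)
  expect_equal(screen_grains(d, cfg), by_hand)

  low <- d; low$confidence <- runif(n, 0, 0.69)
  expect_equal(nrow(screen_grains(low, screening_config())), 0)

  disj <- detections(c(0, 50), c(0, 0), c(10, 60), c(10, 10), 0.9)
  expect_equal(nrow(screen_grains(disj, screening_config())), 2)

  # pairwise occlusion filter drops both members of an overlapping pair
  # (pair IoU 0.43: below the 0.8 NMS threshold, above the 0.3 filter)
  pair <- detections(c(0, 8, 70), c(0, 0, 0), c(20, 28, 90), c(20, 20, 20), 0.9)
  kept <- screen_grains(pair, screening_config(max_pairwise_iou = 0.3))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$x_min, 70)
})

test_that("cropping pads and clips against the image border", {
  img <- board_image(100, 100)
  b <- detections(10, 10, 20, 20, 1)
  expect_equal(dim(crop_grain(img, b, 0)$crop)[1:2], c(10, 10))
  cr2 <- crop_grain(img, b, 2)
  expect_equal(dim(cr2$crop)[1:2], c(14, 14))
  expect_equal(cr2$offset, c(row = 8, col = 8))

  edge <- detections(0, 40, 8, 50, 1)
  cre <- crop_grain(img, edge, 2)
  expect_equal(cre$offset[["col"]], 0)           # clipped at the left edge
  expect_equal(dim(cre$crop)[1:2], c(14, 10))
  expect_error(crop_grain(img, detections(150, 150, 160, 160, 1), 0),
               "outside")
})

test_that("grain segmentation keeps the main body and drops specks", {
  ec <- ellipse_crop(30, 44, 15, 22, 15, 5, 10)
  mask <- segment_grain(ec$crop)
  dice <- 2 * sum(mask & ec$truth) / (sum(mask) + sum(ec$truth))
  expect_gte(dice, 0.95)

  speck <- ec$crop
  speck[2, 2:4, ] <- rep(c(0.85, 0.72, 0.35), each = 3)
  m2 <- segment_grain(speck)
  expect_false(any(m2[1:3, 1:6]))                # speck filtered out
  expect_gte(sum(m2 & ec$truth) / sum(ec$truth), 0.95)

  expect_error(segment_grain(board_image(20, 20),
                             method = "rgb_range", rgb_lo = c(0.8, 0.8, 0.8),
                             rgb_hi = c(1, 1, 1)),
               "no grain body")
})

test_that("minimum bounding rectangle is exact on blocks and beats no sweep angle", {
  m <- matrix(FALSE, 20, 20); m[6:9, 4:13] <- TRUE   # 10 wide x 4 tall
  r <- min_bounding_rect(m)
  expect_equal(c(r$length_px, r$width_px, r$angle), c(10, 4, 0))
  r90 <- min_bounding_rect(t(m))
  expect_equal(c(r90$length_px, r90$width_px, r90$angle), c(10, 4, 90))

  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  expect_equal(min_bounding_rect(m1)[c("length_px", "width_px")],
               list(length_px = 1, width_px = 1))
  expect_error(min_bounding_rect(matrix(FALSE, 4, 4)), "empty mask")

  for (seed in 1:10) {
    blob <- random_blob(seed)
    if (sum(blob) < 5) next
    got <- min_bounding_rect(blob)
    expect_lte(got$area, sweep_min_rect_area(blob) + 1e-6)
  }
})

test_that("rotated copies of an elongated mask measure consistently", {
  base <- ellipse_crop(60, 60, 30, 30, 22, 6, 0)$truth
  r0 <- min_bounding_rect(base)
  for (th in c(25, 60, 115)) {
    rt <- min_bounding_rect(ellipse_crop(60, 60, 30, 30, 22, 6, th)$truth)
    expect_lt(abs(rt$length_px / r0$length_px - 1), 0.03)
    # the 12 px minor axis carries ~1 px of pixel-corner discretization
    expect_lt(abs(rt$width_px / r0$width_px - 1), 0.10)
  }
})

test_that("measured grain dimensions track the generated sizes in mm", {
  sc <- generate_scene(test_grain_spec(seed = 5, n_grains = 8))
  pel <- pel_density(detect_calibrator(sc$image))
  det <- baseline_detect(sc$image, detect_params(method = "rgb_range"))
  meas <- measure_grains(sc$image, det, screening_config(), pel)
  expect_equal(nrow(meas), 8)
  expect_true(all(meas$length_mm >= meas$width_mm))
  expect_true(all(meas$aspect_ratio >= 1))
  truth <- sc$truth$grains
  # 0.25 mm/px unit-test scale: ~1 px discretization on a 12 px width
  expect_lt(abs(mean(meas$length_mm) / mean(truth$length_mm) - 1), 0.04)
  expect_lt(abs(mean(meas$width_mm) / mean(truth$width_mm) - 1), 0.10)
  expect_error(measure_grains(sc$image, detections(), screening_config(), pel),
               "no measurable grains")
})

test_that("panicle-level stats average per-grain values", {
  one <- tibble::tibble(length_mm = 8, width_mm = 3, aspect_ratio = 8 / 3)
  st1 <- panicle_grain_stats(one)
  expect_equal(st1$n_measured, 1)
  expect_equal(st1$mean_length_mm, 8)

  two <- tibble::tibble(length_mm = c(8, 10), width_mm = c(3, 2),
                        aspect_ratio = c(8 / 3, 10 / 2))
  st2 <- panicle_grain_stats(two)
  expect_equal(st2$mean_length_mm, 9)
  # mean of per-grain aspects, not ratio of means (which would be 3.6)
  expect_equal(st2$mean_aspect, (8 / 3 + 5) / 2)
  expect_error(panicle_grain_stats(two[0, ]), "no measurements")
})
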