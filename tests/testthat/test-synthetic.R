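test_that("scene generation is deterministic and self-consistent", {
  sp <- test_grain_spec(seed = 41)
  s1 <- generate_scene(sp)
  s2 <- generate_scene(sp)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth$grains, s2$truth$grains)
  expect_equal(s1$truth$mm_per_pixel,
               sp$calibrator$real_radius_mm / sp$calibrator$pixel_radius)
  g <- s1$truth$grains
  expect_true(all(g$x_min >= 0 & g$y_min >= 0))
  expect_true(all(g$x_max <= 700 & g$y_max <= 500))
  expect_equal(s1$truth$n_grains, nrow(g))
})

test_that("zero overlap level yields pairwise disjoint truth boxes", {
  for (seed in c(2, 9)) {
    tr <- generate_scene(test_grain_spec(seed = seed, n_grains = 12),
                         render = FALSE)$truth
    d <- truth_boxes(tr)
    for (i in 1:(nrow(d) - 1)) for (j in (i + 1):nrow(d)) {
      expect_equal(box_iou(d[i, ], d[j, ]), 0)
    }
  }
})

test_that("impossible placement requests fail loudly", {
  sp <- test_grain_spec(seed = 1, n_grains = 200,
                        grain_region = list(rows = c(0.4, 0.6), cols = c(0.45, 0.6)),
                        max_attempts = 30L)
  expect_error(generate_scene(sp, render = FALSE), "placement error")
})

test_that("an error-free detector model reproduces the truth boxes", {
  tr <- generate_scene(test_grain_spec(seed = 8, n_grains = 10),
                       render = FALSE)$truth
  det <- simulate_detections(tr, detector_error_model(alpha = 0, jitter_sd = 0),
                             seed = 5)
  expect_equal(nrow(det), 10)
  g <- tr$grains
  expect_equal(det$x_min, g$x_min)
  expect_equal(det$y_max, g$y_max)

  # alpha = 1 on a fully disjoint scene: occlusion 0, nothing is missed
  det2 <- simulate_detections(tr, detector_error_model(alpha = 1), seed = 5)
  expect_equal(nrow(det2), 10)
})

test_that("miss fraction agrees with the analytic mean of alpha x occlusion", {
  specs <- lapply(1:60, function(i) {
    scene_spec(image_size = c(500, 700),
               calibrator = list(center = c(110, 110), pixel_radius = 100,
                                 real_radius_mm = 25),
               stem = list(include = FALSE), n_grains = 15,
               grain_region = list(rows = c(0.05, 0.95), cols = c(0.4, 0.96)),
               overlap_level = 0.4)
  })
  alpha <- 0.8
  miss <- numeric(0); occ <- numeric(0)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]; sp$seed <- 9000L + i
    tr <- generate_scene(sp, render = FALSE)$truth
    det <- simulate_detections(tr, detector_error_model(alpha = alpha),
                               seed = 100L + i)
    miss <- c(miss, tr$n_grains - nrow(det))
    occ <- c(occ, panicletraits:::grain_occlusion(tr))
  }
  p <- alpha * occ                      # per-grain Bernoulli miss probabilities
  expected <- sum(p)
  sd_miss <- sqrt(sum(p * (1 - p)))
  expect_lt(abs(sum(miss) - expected), 2 * sd_miss + 1e-9)
})

test_that("the PMI dataset reproduces the count identity and occlusion trend", {
  specs <- lapply(1:10, function(i) test_grain_spec(n_grains = 12))
  ds0 <- pmi_dataset(specs, detector_error_model(alpha = 0, jitter_sd = 0), seed = 2)
  expect_true(all(ds0$pmi == 1))
  expect_true(all(ds0$n_forecast == ds0$n_actual))

  means <- sapply(c(0.2, 0.4, 0.6), function(ov) {
    sp <- lapply(1:25, function(i) {
      scene_spec(image_size = c(500, 700),
                 calibrator = list(center = c(110, 110), pixel_radius = 100,
                                   real_radius_mm = 25),
                 stem = list(include = FALSE), n_grains = 15,
                 grain_region = list(rows = c(0.05, 0.95), cols = c(0.4, 0.96)),
                 overlap_level = ov)
    })
    ds <- pmi_dataset(sp, detector_error_model(), seed = 31)
    expect_equal(ds$pmi, pmi_from_counts(ds$n_actual, ds$n_forecast))
    mean(ds$pmi)
  })
  expect_true(all(diff(means) < 0))
})

test_that("rendered scenes round-trip through PNG and truth JSON", {
  dir <- withr::local_tempdir()
  sc <- generate_scene(test_grain_spec(seed = 77, n_grains = 4))
  paths <- write_scene(sc, dir)
  expect_true(all(file.exists(paths)))
  img <- read_panicle_image(paths["image"])
  expect_equal(dim(img), dim(sc$image))
  expect_lt(max(abs(img - sc$image)), 1 / 255)   # 8-bit quantization only
  tr <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(tr$n_grains, 4)
  expect_equal(tr$mm_per_pixel, sc$truth$mm_per_pixel)
})
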