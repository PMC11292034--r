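box <- function(x0, y0, x1, y1, conf = 1) {
  detections(x0, y0, x1, y1, conf)
}

test_that("IoU matches unit-pixel counting and is symmetric", {
  a <- box(0, 0, 2, 2)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, box(5, 5, 7, 7)), 0)
  b <- box(1, 0, 3, 2)
  expect_equal(box_iou(a, b), 1 / 3)
  expect_equal(box_iou(a, b), pixel_count_iou(a, b))
  set.seed(7)
  for (k in 1:20) {
    p <- sort(sample(0:30, 2)); q <- sort(sample(0:30, 2))
    r <- sort(sample(0:30, 2)); s <- sort(sample(0:30, 2))
    if (p[1] == p[2] || q[1] == q[2] || r[1] == r[2] || s[1] == s[2]) next
    u <- box(p[1], q[1], p[2], q[2]); v <- box(r[1], s[1], r[2], s[2])
    expect_equal(box_iou(u, v), pixel_count_iou(u, v))
    expect_equal(box_iou(u, v), box_iou(v, u))
  }
})

test_that("IoU decreases monotonically as boxes separate", {
  a <- box(0, 0, 10, 10)
  ious <- sapply(0:12, function(dx) box_iou(a, box(dx, 0, dx + 10, 10)))
  expect_true(all(diff(ious) <= 0))
  expect_equal(ious[1], 1)
  expect_equal(ious[13], 0)
})

test_that("confidence filtering keeps boxes at or above the threshold", {
  d <- detections(c(0, 20, 40), c(0, 0, 0), c(10, 30, 50), c(10, 10, 10),
                  c(0.9, 0.69, 0.71))
  expect_identical(filter_confidence(d, 0), d)
  expect_equal(nrow(filter_confidence(d, 0.7)), 2)
  expect_equal(nrow(filter_confidence(d, 1.0)), 0)
})

test_that("greedy NMS matches an exhaustive reference on random inputs", {
  d1 <- box(0, 0, 10, 10, 0.5)
  expect_equal(nrow(nms(d1, 0.5)), 1)

  two <- detections(c(0, 0), c(0, 0), c(10, 10), c(10, 10), c(0.9, 0.8))
  kept <- nms(two, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$confidence, 0.9)

  for (seed in 1:20) {
    set.seed(seed)
    n <- 5
    x0 <- runif(n, 0, 50); y0 <- runif(n, 0, 50)
    d <- detections(x0, y0, x0 + runif(n, 5, 30), y0 + runif(n, 5, 30),
                    round(runif(n), 3))
    for (thr in c(0.2, 0.5)) {
      got <- nms(d, thr)
      ref <- brute_nms(d, thr)
      expect_equal(got[order(got$x_min), ], ref[order(ref$x_min), ],
                   ignore_attr = TRUE)
      # survivors: subset of input, pairwise IoU <= threshold
      expect_true(all(got$x_min %in% d$x_min))
      if (nrow(got) > 1) {
        M <- outer(seq_len(nrow(got)), seq_len(nrow(got)), function(i, j) {
          box_iou(got[i, ], got[j, ])
        })
        diag(M) <- 0
        expect_lte(max(M), thr)
      }
    }
  }
})

test_that("baseline detector finds each disjoint grain exactly once", {
  blank <- board_image(120, 120)
  expect_equal(nrow(baseline_detect(blank, detect_params(method = "rgb_range"))), 0)

  sc <- generate_scene(test_grain_spec(seed = 31, n_grains = 5))
  det <- baseline_detect(sc$image, detect_params(method = "rgb_range"))
  expect_equal(nrow(det), 5)
  g <- sc$truth$grains
  hits <- sapply(seq_len(nrow(det)), function(i) {
    sum(g$center_col >= det$x_min[i] & g$center_col < det$x_max[i] &
          g$center_row >= det$y_min[i] & g$center_row < det$y_max[i])
  })
  expect_true(all(hits == 1))
  expect_true(all(det$confidence > 0.7))
})

test_that("detection files round-trip and reject malformed boxes", {
  d <- detections(c(1, 15.5), c(2, 20), c(11, 30), c(8, 40.25), c(0.5, 0.875),
                  image_id = c("a", "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections(d, path)
  expect_equal(as.data.frame(read_detections(path)), as.data.frame(d))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("image_id,x_min,y_min,x_max,y_max,confidence",
               "a,10,2,5,8,0.5"), bad)
  expect_error(read_detections(bad), "line 2")
})

test_that("COCO-style JSON bbox x,y,w,h converts to half-open corners", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "images": [{"id": 1, "file_name": "img7.png", "width": 100, "height": 100}],
    "annotations": [{"id": 1, "image_id": 1, "bbox": [10, 20, 30, 40], "score": 0.9}]
  }', path)
  d <- read_detections(path)
  expect_equal(nrow(d), 1)
  expect_equal(d$image_id, "img7.png")
  expect_equal(c(d$x_min, d$y_min, d$x_max, d$y_max), c(10, 20, 40, 60))
  expect_equal(d$confidence, 0.9)
})

test_that("boxes outside the image are clipped or dropped with a warning", {
  d <- detections(c(-5, 90), c(10, 95), c(10, 120), c(20, 130), c(0.8, 0.9))
  expect_warning(out <- clip_detections(detections(-10, -10, -2, -2, 0.5), c(50, 50)),
                 "clipped to empty")
  expect_equal(nrow(out), 0)
  clipped <- clip_detections(d, c(100, 100))
  expect_equal(clipped$x_min, c(0, 90))
  expect_equal(clipped$x_max, c(10, 100))
  expect_equal(clipped$y_max, c(20, 100))
})
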