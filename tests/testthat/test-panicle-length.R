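# build a logical mask from 1-based (row, col) pixel chains
mask_from <- function(H, W, ...) {
  m <- matrix(FALSE, H, W)
  for (px in list(...)) m[px] <- TRUE
  m
}
chain <- function(rows, cols) cbind(rows, cols)

# Y-shaped skeleton: trunk + two diagonal branches of given lengths
y_skeleton <- function(H, W, trunk_col, trunk_rows, junction, len_a, len_b) {
  mask_from(H, W,
    chain(trunk_rows, rep(trunk_col, length(trunk_rows))),
    chain(junction[1], junction[2]),
    chain(junction[1] - seq_len(len_a), junction[2] - seq_len(len_a)),
    chain(junction[1] - seq_len(len_b), junction[2] + seq_len(len_b))
  )
}

test_that("saturation segmentation covers the stem and excludes the calibrator", {
  sc <- generate_scene(panicle_scene_spec(seed = 3))
  img <- sc$image
  stem_px <- img[, , 1] == 0.20 & img[, , 2] == 0.55 & img[, , 3] == 0.15
  mask <- segment_panicle(img)
  expect_gte(sum(mask & stem_px) / sum(stem_px), 0.95)

  cleaned <- clean_mask(mask)
  ctr <- sc$truth$calibrator$center; R <- sc$truth$calibrator$pixel_radius
  rr <- matrix(seq_len(nrow(img)) - 1, nrow(img), ncol(img)) - ctr[1]
  cc <- matrix(rep(seq_len(ncol(img)) - 1, each = nrow(img)), nrow(img), ncol(img)) - ctr[2]
  cal_region <- sqrt(rr^2 + cc^2) <= R + 1
  expect_equal(sum(cleaned & cal_region), 0)

  expect_error(segment_panicle(board_image(60, 60)), "no panicle found")
})

test_that("mask cleaning removes specks, fills holes, and keeps the largest part", {
  m <- matrix(FALSE, 200, 200)
  m[50:149, 50:149] <- TRUE                     # 10,000 px component
  m[80:84, 80:83] <- FALSE                      # 20 px hole
  specks <- list(c(5, 5), c(10, 190), c(190, 10), c(195, 195), c(3, 100))
  for (s in specks) m[s[1]:(s[1] + 2), s[2]:(s[2] + 2)] <- TRUE  # <50 px each
  out <- clean_mask(m, min_area = 100)
  expect_equal(sum(out), 100 * 100)             # specks gone, hole filled
  for (s in specks) expect_false(out[s[1], s[2]])

  noise <- matrix(FALSE, 50, 50); noise[cbind(c(3, 30), c(3, 30))] <- TRUE
  expect_error(clean_mask(noise, min_area = 100), "no panicle found")
})

test_that("thinning produces an idempotent one-pixel-wide skeleton", {
  bar <- matrix(FALSE, 20, 120); bar[9:11, 11:110] <- TRUE
  sk <- skeletonize(bar)
  expect_true(sum(sk) >= 96 && sum(sk) <= 102)   # end erosion of ~thickness/2
  expect_equal(nrow(find_endpoints(sk)), 2)
  expect_identical(skeletonize(sk), sk)

  line <- mask_from(10, 60, chain(rep(5, 50), 6:55))
  expect_identical(skeletonize(line), line)

  disk <- ellipse_crop(40, 40, 20, 20, 10, 10, 0)$truth
  skd <- skeletonize(disk)
  expect_gte(sum(skd), 1)
  expect_lte(sum(skd), 0.1 * sum(disk))

  for (seed in 1:6) {
    blob <- random_blob(seed)
    if (!any(blob)) next
    expect_equal(count_components_8(skeletonize(blob)), count_components_8(blob))
  }
})

test_that("endpoints are pixels with exactly one 8-neighbor", {
  line <- mask_from(10, 60, chain(rep(5, 50), 6:55))
  ep <- find_endpoints(line)
  expect_equal(nrow(ep), 2)
  expect_equal(sort(ep$col), c(5, 54))          # 0-based

  ring <- matrix(FALSE, 20, 20)
  ring[5, 5:15] <- TRUE; ring[15, 5:15] <- TRUE
  ring[5:15, 5] <- TRUE; ring[5:15, 15] <- TRUE
  expect_equal(nrow(find_endpoints(ring)), 0)

  y <- y_skeleton(80, 80, 40, 41:70, c(40, 40), 20, 12)
  epy <- find_endpoints(y)
  expect_equal(nrow(epy), 3)
  expect_equal(epy$row[1], 69)                  # bottom-most first
})

test_that("A* path lengths equal BFS shortest paths", {
  line <- mask_from(10, 60, chain(rep(5, 50), 6:55))
  same <- astar_path(line, c(4, 20), c(4, 20))
  expect_equal(same$pixel_count, 1)
  full <- astar_path(line, c(4, 5), c(4, 54))
  expect_equal(full$pixel_count, 50)

  two <- mask_from(10, 30, chain(rep(3, 5), 2:6), chain(rep(8, 5), 20:24))
  unr <- astar_path(two, c(2, 1), c(7, 19))
  expect_false(unr$reachable)
  expect_true(is.na(unr$pixel_count))

  for (seed in 1:20) {
    sk <- random_skeleton(seed)
    if (sum(sk) < 2) next
    pr <- random_endpoints_pair(sk, seed + 1000)
    got <- astar_path(sk, pr$start, pr$goal)
    ref <- bfs_path_length(sk, pr$start, pr$goal)
    if (is.infinite(ref)) {
      expect_false(got$reachable)
    } else {
      expect_equal(got$pixel_count, ref)
      # path is a valid 8-connected simple chain
      d <- diff(got$pixels)
      expect_true(all(pmax(abs(d[, 1]), abs(d[, 2])) == 1))
      expect_equal(anyDuplicated(as.data.frame(got$pixels)), 0)
    }
  }
})

test_that("the main path starts at the bottom and takes the longest branch", {
  line <- mask_from(60, 10, chain(6:55, rep(5, 50)))
  mp <- main_path(line)
  expect_equal(mp$pixel_count, 50)
  expect_equal(mp$pixels[1, ], c(row = 54, col = 4), ignore_attr = TRUE)

  y <- y_skeleton(150, 220, 100, 100:140, c(99, 100), 80, 60)
  mpy <- main_path(y)
  ref_a <- bfs_path_length(y, c(139, 99), c(99 - 80 - 1, 100 - 80 - 1))
  ref_b <- bfs_path_length(y, c(139, 99), c(99 - 60 - 1, 100 + 60 - 1))
  expect_equal(mpy$pixel_count, ref_a)
  expect_gt(ref_a, ref_b)
  expect_equal(as.numeric(mpy$pixels[nrow(mpy$pixels), 2]), 100 - 80 - 1)

  # left-right mirroring preserves the main-path length
  mirrored <- y[, rev(seq_len(ncol(y)))]
  expect_equal(main_path(mirrored)$pixel_count, mpy$pixel_count)

  expect_error(main_path(mask_from(10, 10, chain(5, 5))), "degenerate skeleton")
  # with one candidate, only the unreachable top segment is considered
  two <- mask_from(20, 40, chain(rep(15, 6), 2:7), chain(rep(3, 6), 30:35))
  expect_error(main_path(two, n_candidates = 1), "disconnected skeleton")
})

test_that("path length converts to mm by pixel count or euclidean steps", {
  pel <- pel_density(125)                        # 0.2 mm/px
  vert <- mask_from(120, 10, chain(11:110, rep(5, 100)))
  pv <- astar_path(vert, c(10, 4), c(109, 4))
  expect_equal(panicle_length_mm(pv, pel)$length_mm, 20)
  expect_equal(panicle_length_mm(pv, pel, "euclidean_steps")$length_mm, 20)

  diag_m <- mask_from(120, 120, chain(11:110, 11:110))
  pd <- astar_path(diag_m, c(10, 10), c(109, 109))
  expect_equal(pd$pixel_count, 100)
  expect_equal(panicle_length_mm(pd, pel)$length_mm, 20)
  expect_equal(panicle_length_mm(pd, pel, "euclidean_steps")$length_mm,
               (1 + 99 * sqrt(2)) * 0.2)

  single <- astar_path(vert, c(50, 4), c(50, 4))
  expect_equal(panicle_length_mm(single, pel)$length_mm, pel$mm_per_pixel)
})

test_that("main-path pixel count tracks the generated stem skeleton", {
  sc <- generate_scene(panicle_scene_spec(seed = 12))
  res <- measure_panicle_length(sc$image, pel_density(detect_calibrator(sc$image)))
  expect_lt(abs(res$length_px / sc$truth$stem$skeleton_px - 1), 0.03)
  # bottom-to-top orientation
  expect_gt(res$start[1], res$end[1])
})
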