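# Small, fast scene variants for unit tests. The full-size study
# conditions (scene_spec() defaults) are exercised in test-acceptance.R;
# unit tests use a 500x700 px variant (0.25 mm/px, grains ~36x12 px) to
# keep the suite quick, at correspondingly coarser discretization.

test_grain_spec <- function(seed = 1L, n_grains = 8,
                            grain_region = list(rows = c(0.05, 0.95),
                                                cols = c(0.40, 0.96)), ...) {
  scene_spec(
    image_size = c(500, 700),
    calibrator = list(center = c(110, 110), pixel_radius = 100, real_radius_mm = 25),
    stem = list(include = FALSE),
    n_grains = n_grains,
    grain_region = grain_region,
    seed = seed,
    ...
  )
}

# a hard-edged ellipse crop plus its exact center-inside truth mask
ellipse_crop <- function(H, W, cr, cc, a, b, theta_deg,
                         board = c(0.72, 0.72, 0.72), grain = c(0.85, 0.72, 0.35)) {
  th <- theta_deg * pi / 180
  ry <- matrix(seq_len(H) - 0.5, H, W) - cr
  cx <- matrix(rep(seq_len(W) - 0.5, each = H), H, W) - cc
  u <- cx * cos(th) + ry * sin(th)
  v <- -cx * sin(th) + ry * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  img <- array(rep(board, each = H * W), dim = c(H, W, 3))
  for (ch in 1:3) {
    chan <- img[, , ch]
    chan[inside] <- grain[ch]
    img[, , ch] <- chan
  }
  list(crop = img, truth = inside)
}

# a plain RGB image: gray board with an optional red disk
board_image <- function(H = 200, W = 200, disk = NULL, board = c(0.72, 0.72, 0.72)) {
  img <- array(rep(board, each = H * W), dim = c(H, W, 3))
  if (!is.null(disk)) {
    rr <- matrix(seq_len(H) - 0.5, H, W) - disk$center[1]
    cc <- matrix(rep(seq_len(W) - 0.5, each = H), H, W) - disk$center[2]
    inside <- sqrt(rr^2 + cc^2) <= disk$radius
    for (ch in 1:3) {
      chan <- img[, , ch]
      chan[inside] <- disk$color[ch]
      img[, , ch] <- chan
    }
  }
  img
}
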