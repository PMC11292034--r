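# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package (exhaustive search, BFS,
# rasterization) so agreement is meaningful.

# IoU by counting unit pixels on a grid (integer boxes only)
pixel_count_iou <- function(a, b) {
  lim <- max(a$x_max, b$x_max, a$y_max, b$y_max)
  g1 <- matrix(FALSE, lim, lim); g2 <- matrix(FALSE, lim, lim)
  g1[(a$y_min + 1):a$y_max, (a$x_min + 1):a$x_max] <- TRUE
  g2[(b$y_min + 1):b$y_max, (b$x_min + 1):b$x_max] <- TRUE
  sum(g1 & g2) / sum(g1 | g2)
}

# union area of integer boxes by rasterization
raster_union_area <- function(d) {
  lim_x <- max(d$x_max); lim_y <- max(d$y_max)
  g <- matrix(FALSE, lim_y, lim_x)
  for (i in seq_len(nrow(d))) {
    g[(d$y_min[i] + 1):d$y_max[i], (d$x_min[i] + 1):d$x_max[i]] <- TRUE
  }
  sum(g)
}

# naive O(n^2) greedy NMS with the same ordering contract
brute_nms <- function(d, thr) {
  ord <- order(-d$confidence, d$x_min, d$y_min)
  d <- d[ord, , drop = FALSE]
  keep <- rep(NA, 0)
  for (i in seq_len(nrow(d))) {
    ok <- TRUE
    for (k in keep) {
      if (box_iou(d[k, ], d[i, ]) > thr) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  d[keep, , drop = FALSE]
}

# BFS shortest-path pixel count on an 8-connected skeleton grid
# (0-based start/goal); Inf when unreachable
bfs_path_length <- function(sk, start, goal) {
  H <- nrow(sk); W <- ncol(sk)
  dist <- matrix(Inf, H, W)
  s <- start + 1; g <- goal + 1
  dist[s[1], s[2]] <- 1
  queue <- matrix(s, ncol = 2)
  while (nrow(queue) > 0) {
    nxt <- matrix(numeric(), 0, 2)
    for (q in seq_len(nrow(queue))) {
      r <- queue[q, 1]; c <- queue[q, 2]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        nr <- r + dr; nc <- c + dc
        if (nr < 1 || nr > H || nc < 1 || nc > W) next
        if (!sk[nr, nc] || dist[nr, nc] < Inf) next
        dist[nr, nc] <- dist[r, c] + 1
        nxt <- rbind(nxt, c(nr, nc))
      }
    }
    queue <- nxt
  }
  dist[g[1], g[2]]
}

# min-area enclosing rectangle by exhaustive angle sweep over the pixel
# corner points (step degrees)
sweep_min_rect_area <- function(mask, step = 0.1) {
  px <- which(mask, arr.ind = TRUE)
  x <- c(px[, 2] - 1, px[, 2], px[, 2] - 1, px[, 2])
  y <- c(px[, 1] - 1, px[, 1] - 1, px[, 1], px[, 1])
  best <- Inf
  for (deg in seq(0, 180 - step, by = step)) {
    th <- deg * pi / 180
    u <- x * cos(th) + y * sin(th)
    v <- -x * sin(th) + y * cos(th)
    a <- (max(u) - min(u)) * (max(v) - min(v))
    if (a < best) best <- a
  }
  best
}

# number of 8-connected components of a logical mask
count_components_8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    if (lab[idx[k, 1], idx[k, 2]] > 0L) next
    nxt <- nxt + 1L
    stack <- matrix(idx[k, ], ncol = 2)
    lab[idx[k, 1], idx[k, 2]] <- nxt
    while (nrow(stack) > 0) {
      r <- stack[1, 1]; c <- stack[1, 2]
      stack <- stack[-1, , drop = FALSE]
      for (dr in -1:1) for (dc in -1:1) {
        nr <- r + dr; nc <- c + dc
        if (nr < 1 || nr > nrow(mask) || nc < 1 || nc > ncol(mask)) next
        if (mask[nr, nc] && lab[nr, nc] == 0L) {
          lab[nr, nc] <- nxt
          stack <- rbind(stack, c(nr, nc))
        }
      }
    }
  }
  nxt
}

# random blob mask: union of a few random ellipses
random_blob <- function(seed, size = 40) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  for (i in 1:sample(2:4, 1)) {
    cr <- runif(1, size * 0.3, size * 0.7)
    cc <- runif(1, size * 0.3, size * 0.7)
    a <- runif(1, 3, size * 0.25); b <- runif(1, 2, a)
    th <- runif(1, 0, pi)
    rr <- matrix(seq_len(size) - 0.5, size, size) - cr
    cm <- matrix(rep(seq_len(size) - 0.5, each = size), size, size) - cc
    u <- cm * cos(th) + rr * sin(th)
    v <- -cm * sin(th) + rr * cos(th)
    m <- m | ((u / a)^2 + (v / b)^2 <= 1)
  }
  m
}

# random skeleton: thinned random blob
random_skeleton <- function(seed, size = 50) {
  skeletonize(random_blob(seed, size))
}

# two random foreground pixels of a skeleton (0-based)
random_endpoints_pair <- function(sk, seed) {
  set.seed(seed)
  fg <- which(sk, arr.ind = TRUE)
  i <- sample.int(nrow(fg), 2, replace = nrow(fg) == 1)
  list(start = fg[i[1], ] - 1, goal = fg[i[2], ] - 1)
}
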