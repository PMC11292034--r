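# Panicle length is measured on the skeleton of the segmented panicle:
# segment by saturation, clean the mask, thin it to a 1-pixel-wide
# 8-connected skeleton, then take the bottom endpoint and search (A*) the
# shortest path to each of the top-most endpoints; the candidate path with
# the most pixels is the main path, and its pixel count times the pel
# density is the panicle length.

#' Segment the panicle from the background board
#'
#' Thresholds the saturation (S) channel of the HSV image: the panicle
#' (stem and grains) is colored and therefore saturated, while the board
#' is nearly gray. The threshold is Otsu's by default.
#'
#' @param image RGB image array.
#' @param s_threshold `"otsu"` or a fixed saturation threshold in `[0, 1]`.
#' @return Logical foreground mask.
#' @export
segment_panicle <- function(image, s_threshold = "otsu") {
  s <- image_hsv(image)$s
  thr <- if (identical(s_threshold, "otsu")) otsu_threshold(s) else s_threshold
  mask <- s > thr
  if (!any(mask)) stopf("no panicle found: empty saturation foreground")
  mask
}

#' Clean a panicle mask
#'
#' Removes small components (noise, impurities, and the calibration
#' object), fills interior holes to smooth the silhouette, and keeps the
#' largest remaining component (one panicle per image by protocol).
#'
#' @param mask Logical mask.
#' @param min_area Minimum component area kept, in px^2. `NULL` (default)
#'   scales the reference value of 100 px^2 at 3000x4000 input resolution
#'   by the actual image area, with a floor of 16 px^2.
#' @param fill_holes Fill interior background holes (default `TRUE`).
#' @return Logical mask containing a single component.
#' @export
clean_mask <- function(mask, min_area = NULL, fill_holes = TRUE) {
  if (is.null(min_area)) {
    min_area <- max(16, round(100 * nrow(mask) * ncol(mask) / (3000 * 4000)))
  }
  lab <- label_components(mask)
  if (max(lab) == 0L) stopf("no panicle found: empty mask")
  areas <- tabulate(lab[lab > 0L])
  small <- which(areas < min_area)
  if (length(small)) lab[lab %in% small] <- 0L
  if (!any(lab > 0L)) stopf("no panicle found: every component below min_area")
  mask <- lab > 0L
  if (fill_holes) {
    mask <- matrix(as.logical(as.integer(EBImage::fillHull(EBImage::Image(mask * 1)))),
                   nrow = nrow(mask))
  }
  lab <- label_components(mask)
  areas <- tabulate(lab[lab > 0L])
  lab == which.max(areas)
}

# neighbor-shifted copy of a logical matrix: out[r, c] = m[r + dr, c + dc]
shift_mask <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  sr <- max(1, 1 + dr):min(H, H + dr)
  sc <- max(1, 1 + dc):min(W, W + dc)
  out[sr - dr, sc - dc] <- m[sr, sc]
  out
}

# the 8 neighbors in Zhang-Suen order P2..P9 = N, NE, E, SE, S, SW, W, NW
zs_neighbors <- function(m) {
  list(
    shift_mask(m, -1, 0), shift_mask(m, -1, 1), shift_mask(m, 0, 1),
    shift_mask(m, 1, 1), shift_mask(m, 1, 0), shift_mask(m, 1, -1),
    shift_mask(m, 0, -1), shift_mask(m, -1, -1)
  )
}

#' Morphological thinning to a 1-pixel-wide skeleton
#'
#' Zhang–Suen thinning with sequential deletion: in each sub-iteration
#' the candidate boundary pixels are found with the vectorized Zhang–Suen
#' conditions, then removed one at a time in scan order with the
#' conditions re-checked against the updated image. The re-check is what
#' preserves topology: purely parallel deletion can annihilate 2-pixel-wide
#' structures (a 2x2 block, and ultimately a disk) entirely, whereas a
#' sequential pass can never delete the last pixels of a component. The
#' result is a 1-pixel-wide, 8-connected skeleton and thinning is
#' idempotent: re-thinning a skeleton changes nothing.
#'
#' @param mask Logical mask (ideally a single cleaned component).
#' @return Logical skeleton matrix.
#' @export
skeletonize <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  mp <- matrix(FALSE, H + 2, W + 2)
  mp[2:(H + 1), 2:(W + 1)] <- mask
  Hp <- H + 2
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      P <- zs_neighbors(mp)
      B <- Reduce(`+`, P)
      seq9 <- c(P, P[1])
      A <- Reduce(`+`, lapply(1:8, function(i) (!seq9[[i]]) & seq9[[i + 1]]))
      if (sub == 1) {
        cond <- mp & B >= 2 & B <= 6 & A == 1 &
          !(P[[1]] & P[[3]] & P[[5]]) & !(P[[3]] & P[[5]] & P[[7]])
      } else {
        cond <- mp & B >= 2 & B <= 6 & A == 1 &
          !(P[[1]] & P[[3]] & P[[7]]) & !(P[[1]] & P[[5]] & P[[7]])
      }
      for (idx in which(cond)) {
        r <- ((idx - 1L) %% Hp) + 1L
        c <- ((idx - 1L) %/% Hp) + 1L
        p1 <- mp[r - 1, c];     p2 <- mp[r - 1, c + 1]
        p3 <- mp[r, c + 1];     p4 <- mp[r + 1, c + 1]
        p5 <- mp[r + 1, c];     p6 <- mp[r + 1, c - 1]
        p7 <- mp[r, c - 1];     p8 <- mp[r - 1, c - 1]
        b <- p1 + p2 + p3 + p4 + p5 + p6 + p7 + p8
        if (b < 2 || b > 6) next
        a <- (!p1 && p2) + (!p2 && p3) + (!p3 && p4) + (!p4 && p5) +
          (!p5 && p6) + (!p6 && p7) + (!p7 && p8) + (!p8 && p1)
        if (a != 1) next
        ok <- if (sub == 1) {
          !(p1 && p3 && p5) && !(p3 && p5 && p7)
        } else {
          !(p1 && p3 && p7) && !(p1 && p5 && p7)
        }
        if (ok) {
          mp[idx] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  mp[2:(H + 1), 2:(W + 1)]
}

#' Skeleton endpoints
#'
#' An endpoint is a foreground skeleton pixel with exactly one foreground
#' pixel among its 8 neighbors.
#'
#' @param sk Logical skeleton matrix.
#' @return Tibble with 0-based `row`, `col`, sorted by row descending
#'   (bottom first) then col ascending. May be empty (closed loops).
#' @export
find_endpoints <- function(sk) {
  B <- Reduce(`+`, zs_neighbors(sk))
  ep <- which(sk & B == 1L, arr.ind = TRUE)
  out <- tibble::tibble(row = ep[, 1] - 1, col = ep[, 2] - 1)
  out[order(-out$row, out$col), ]
}

# 8-neighborhood scan order N, NE, E, SE, S, SW, W, NW as (dr, dc)
.nbr_dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
.nbr_dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

#' A* shortest path on a skeleton grid
#'
#' Finds a minimum-pixel-count 8-connected path between two skeleton
#' pixels. Every move (straight or diagonal) costs 1, so the optimized
#' quantity is the number of pixels on the path; the heuristic is the
#' Chebyshev distance, which is admissible under unit cost, so the
#' returned path length is exactly the shortest. Ties are resolved
#' deterministically (first-found open node; neighbors scanned N, NE, E,
#' SE, S, SW, W, NW).
#'
#' @param sk Logical skeleton matrix.
#' @param start,goal 0-based `(row, col)` of foreground pixels.
#' @return An object of class `skeleton_path`: list with `reachable`,
#'   `pixels` (matrix of 0-based `(row, col)`, start to goal), and
#'   `pixel_count`. If the goal cannot be reached, `reachable` is `FALSE`
#'   (not an error).
#' @export
astar_path <- function(sk, start, goal) {
  H <- nrow(sk); W <- ncol(sk)
  s <- c(start[1] + 1, start[2] + 1)
  g <- c(goal[1] + 1, goal[2] + 1)
  if (!sk[s[1], s[2]] || !sk[g[1], g[2]]) {
    stopf("start and goal must be foreground skeleton pixels")
  }
  idm <- matrix(0L, H, W)
  fg <- which(sk)
  idm[fg] <- seq_along(fg)
  n <- length(fg)
  rows <- ((fg - 1L) %% H) + 1L
  cols <- ((fg - 1L) %/% H) + 1L
  cheb <- pmax(abs(rows - g[1]), abs(cols - g[2]))
  sid <- idm[s[1], s[2]]; gid <- idm[g[1], g[2]]
  gsc <- rep(Inf, n); fsc <- rep(Inf, n)
  parent <- integer(n)
  open <- logical(n); closed <- logical(n)
  gsc[sid] <- 0; fsc[sid] <- cheb[sid]; open[sid] <- TRUE
  found <- FALSE
  while (any(open)) {
    oi <- which(open)
    cur <- oi[which.min(fsc[oi])]
    if (cur == gid) { found <- TRUE; break }
    open[cur] <- FALSE; closed[cur] <- TRUE
    r <- rows[cur]; cc <- cols[cur]
    for (k in 1:8) {
      nr <- r + .nbr_dr[k]; nc <- cc + .nbr_dc[k]
      if (nr < 1L || nr > H || nc < 1L || nc > W) next
      nb <- idm[nr, nc]
      if (nb == 0L || closed[nb]) next
      ng <- gsc[cur] + 1
      if (ng < gsc[nb]) {
        gsc[nb] <- ng
        fsc[nb] <- ng + cheb[nb]
        parent[nb] <- cur
        open[nb] <- TRUE
      }
    }
  }
  if (!found) {
    return(structure(list(reachable = FALSE, pixels = NULL, pixel_count = NA_integer_),
                     class = "skeleton_path"))
  }
  chain <- integer(0)
  cur <- gid
  while (cur != 0L) {
    chain <- c(cur, chain)
    if (cur == sid) break
    cur <- parent[cur]
  }
  px <- cbind(row = rows[chain] - 1L, col = cols[chain] - 1L)
  structure(list(reachable = TRUE, pixels = px, pixel_count = nrow(px)),
            class = "skeleton_path")
}

#' @export
print.skeleton_path <- function(x, ...) {
  if (!x$reachable) {
    cat("<skeleton_path> unreachable\n")
  } else {
    cat(sprintf("<skeleton_path> %d pixels, (%d,%d) -> (%d,%d)\n",
                x$pixel_count, x$pixels[1, 1], x$pixels[1, 2],
                x$pixels[nrow(x$pixels), 1], x$pixels[nrow(x$pixels), 2]))
  }
  invisible(x)
}

#' Main path of a panicle skeleton
#'
#' The measurement strategy: the bottom-most endpoint is the start (tie:
#' smallest column); the candidates are the up-to-`n_candidates` top-most
#' endpoints (smallest row, excluding the start); the shortest path to
#' each reachable candidate is computed with [astar_path()], and the path
#' with the highest pixel count is the main path (tie: first candidate in
#' sorted order).
#'
#' @param sk Logical skeleton matrix.
#' @param n_candidates Number of top endpoints considered (default 20).
#' @return The winning `skeleton_path`.
#' @export
main_path <- function(sk, n_candidates = 20) {
  ep <- find_endpoints(sk)
  if (nrow(ep) < 2L) stopf("degenerate skeleton: fewer than 2 endpoints")
  start <- c(ep$row[1], ep$col[1])         # bottom-most, then smallest col
  rest <- ep[-1, ]
  rest <- rest[order(rest$row, rest$col), ]
  cand <- utils::head(rest, n_candidates)
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    p <- astar_path(sk, start, c(cand$row[i], cand$col[i]))
    if (!p$reachable) next
    if (is.null(best) || p$pixel_count > best$pixel_count) best <- p
  }
  if (is.null(best)) stopf("disconnected skeleton: no candidate endpoint reachable")
  best
}

# length in pixels of a skeleton path under either convention
path_px_length <- function(path, mode) {
  px <- path$pixels
  if (mode == "pixel_count" || nrow(px) == 1L) {
    return(path$pixel_count)
  }
  1 + sum(sqrt(diff(px[, 1])^2 + diff(px[, 2])^2))
}

#' Convert a skeleton path to a physical panicle length
#'
#' In the default `"pixel_count"` mode the length in pixels is the number
#' of pixels on the path (the quantity the main-path search optimizes);
#' `"euclidean_steps"` counts the starting pixel plus per-step lengths
#' (1 for straight, √2 for diagonal moves), so a straight N-pixel path
#' measures N in both modes while diagonal segments are not under-counted.
#'
#' @param path A reachable `skeleton_path`.
#' @param pel A [pel_density()].
#' @param mode `"pixel_count"` (default) or `"euclidean_steps"`.
#' @return An object of class `panicle_length_result`: list with `path`,
#'   `length_px`, `length_mm`, `start`, `end`, `mode`.
#' @export
panicle_length_mm <- function(path, pel, mode = c("pixel_count", "euclidean_steps")) {
  mode <- match.arg(mode)
  stopifnot(inherits(path, "skeleton_path"), path$reachable,
            inherits(pel, "pel_density"))
  px <- path$pixels
  length_px <- path_px_length(path, mode)
  structure(
    list(path = path, length_px = length_px,
         length_mm = length_px * pel$mm_per_pixel,
         start = px[1, ], end = px[nrow(px), ], mode = mode),
    class = "panicle_length_result"
  )
}

#' @export
print.panicle_length_result <- function(x, ...) {
  cat(sprintf("<panicle_length> %.1f px = %.2f mm (%s mode)\n",
              x$length_px, x$length_mm, x$mode))
  invisible(x)
}

#' Measure panicle length from an image
#'
#' Convenience wrapper chaining [segment_panicle()], [clean_mask()],
#' [skeletonize()], [main_path()] and [panicle_length_mm()].
#'
#' @param image RGB image array.
#' @param pel A [pel_density()].
#' @param s_threshold Passed to [segment_panicle()].
#' @param min_area,fill_holes Passed to [clean_mask()].
#' @param n_candidates Passed to [main_path()].
#' @param mode Passed to [panicle_length_mm()].
#' @return A `panicle_length_result`.
#' @export
measure_panicle_length <- function(image, pel, s_threshold = "otsu",
                                   min_area = NULL, fill_holes = TRUE,
                                   n_candidates = 20,
                                   mode = "pixel_count") {
  mask <- segment_panicle(image, s_threshold)
  mask <- clean_mask(mask, min_area, fill_holes)
  sk <- skeletonize(mask)
  panicle_length_mm(main_path(sk, n_candidates), pel, mode)
}
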