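# Planar distance primitives used by the grid-coverage metric and the
# scan-path generator. All coordinates are 0-based pixels, x to the right,
# y downward. Tiles and boxes follow raster conventions: a tile anchored at
# (x0, y0) with side `cell` owns the pixel lattice points
# x0 .. min(x0 + cell, width) - 1 (and likewise in y).

# Distance from points (px, py) to the segment (x1,y1)-(x2,y2); vectorised
# over points. Degenerate segments (zero length) reduce to point distance.
dist_point_seg <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) {
    return(sqrt((px - x1)^2 + (py - y1)^2))
  }
  t <- clamp(((px - x1) * dx + (py - y1) * dy) / len2, 0, 1)
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# Minimum distance between one segment and many axis-aligned closed
# rectangles [rx0, rx1] x [ry0, ry1]. The squared distance along the segment
# parameter t is convex and piecewise quadratic; its minimum lies at an end
# point, at a boundary-line crossing, or at the stationary point of one of
# the four corner regimes, so evaluating the true distance at those <= 10
# candidate t values is exact.
dist_seg_rect <- function(x1, y1, x2, y2, rx0, ry0, rx1, ry1) {
  dx <- x2 - x1
  dy <- y2 - y1
  k <- length(rx0)
  cand <- matrix(NA_real_, nrow = k, ncol = 10)
  cand[, 1] <- 0
  cand[, 2] <- 1
  if (dx != 0) {
    cand[, 3] <- (rx0 - x1) / dx
    cand[, 4] <- (rx1 - x1) / dx
  }
  if (dy != 0) {
    cand[, 5] <- (ry0 - y1) / dy
    cand[, 6] <- (ry1 - y1) / dy
  }
  len2 <- dx * dx + dy * dy
  if (len2 > 0) {
    # stationary points of (A + B t)^2 + (C + D t)^2 for the four corners
    corners_x <- cbind(rx0, rx0, rx1, rx1)
    corners_y <- cbind(ry0, ry1, ry0, ry1)
    for (j in 1:4) {
      a <- x1 - corners_x[, j]
      c <- y1 - corners_y[, j]
      cand[, 6 + j] <- -(a * dx + c * dy) / len2
    }
  }
  cand[is.na(cand)] <- 0
  cand <- clamp(cand, 0, 1)
  best <- rep(Inf, k)
  for (j in seq_len(ncol(cand))) {
    t <- cand[, j]
    px <- x1 + t * dx
    py <- y1 + t * dy
    ex <- pmax(0, pmax(rx0 - px, px - rx1))
    ey <- pmax(0, pmax(ry0 - py, py - ry1))
    best <- pmin(best, ex * ex + ey * ey)
  }
  sqrt(best)
}

#' Grid tiles of an image and their lung membership
#'
#' Divides a `width` x `height` pixel raster into `cell` x `cell` tiles
#' anchored at the image origin. A tile is a lung tile when its centre pixel
#' (offset `floor(cell / 2)` from the tile origin) lies inside the image and
#' inside the lung mask.
#'
#' @param mask Logical matrix of dimension `height` x `width` (`mask[y + 1,
#'   x + 1]` is `TRUE` for lung pixels), as produced by [make_lung_mask()].
#' @param cell Tile side length in pixels.
#' @return A tibble with one row per tile: `tile` (1-based index), `x0`,
#'   `y0` (tile origin), `cx`, `cy` (centre pixel), and `lung` (logical).
#'   Grid dimensions are attached as attributes `nx`, `ny`, `width`,
#'   `height`, `cell`.
#' @export
grid_tiles <- function(mask, cell = 50) {
  assert_that(is.matrix(mask), "`mask` must be a matrix", "cadgaze_input")
  assert_that(is_number(cell) && cell >= 1, "`cell` must be a positive number",
              "cadgaze_input")
  height <- nrow(mask)
  width <- ncol(mask)
  nx <- ceiling(width / cell)
  ny <- ceiling(height / cell)
  j <- rep(seq_len(nx) - 1L, times = ny)
  i <- rep(seq_len(ny) - 1L, each = nx)
  x0 <- j * cell
  y0 <- i * cell
  cx <- x0 + floor(cell / 2)
  cy <- y0 + floor(cell / 2)
  in_img <- cx < width & cy < height
  lung <- rep(FALSE, length(x0))
  idx <- which(in_img)
  lung[idx] <- mask[cbind(cy[idx] + 1L, cx[idx] + 1L)] != 0
  out <- tibble::tibble(tile = seq_along(x0), x0 = x0, y0 = y0,
                        cx = cx, cy = cy, lung = lung)
  attr(out, "nx") <- nx
  attr(out, "ny") <- ny
  attr(out, "width") <- width
  attr(out, "height") <- height
  attr(out, "cell") <- cell
  out
}

# Incrementally mark tiles reached by one gaze segment dilated by `buffer`.
# `covered` is a logical vector over all tiles; only tiles with
# `track = TRUE` (normally the lung tiles) are ever tested or updated.
# Coverage is pixel-exact: a tile counts as covered when at least one of its
# lattice pixels lies within `buffer` (inclusive) of the segment. The cheap
# bound uses the convex hull of the tile's pixels; only distances within
# sqrt(2)/2 of the buffer need an explicit lattice check.
cover_segment <- function(covered, track, x1, y1, x2, y2, tiles, buffer) {
  nx <- attr(tiles, "nx")
  ny <- attr(tiles, "ny")
  cell <- attr(tiles, "cell")
  width <- attr(tiles, "width")
  height <- attr(tiles, "height")
  pad <- buffer + 1
  j0 <- max(0L, floor((min(x1, x2) - pad) / cell))
  j1 <- min(nx - 1L, floor((max(x1, x2) + pad) / cell))
  i0 <- max(0L, floor((min(y1, y2) - pad) / cell))
  i1 <- min(ny - 1L, floor((max(y1, y2) + pad) / cell))
  if (j1 < j0 || i1 < i0) return(covered)
  jj <- rep(j0:j1, times = i1 - i0 + 1L)
  ii <- rep(i0:i1, each = j1 - j0 + 1L)
  idx <- ii * nx + jj + 1L
  idx <- idx[track[idx] & !covered[idx]]
  if (length(idx) == 0L) return(covered)
  rx0 <- tiles$x0[idx]
  ry0 <- tiles$y0[idx]
  rx1 <- pmin(rx0 + cell, width) - 1
  ry1 <- pmin(ry0 + cell, height) - 1
  d <- dist_seg_rect(x1, y1, x2, y2, rx0, ry0, rx1, ry1)
  hit <- d <= buffer - 0.75
  marginal <- which(!hit & d <= buffer + 1e-9)
  for (m in marginal) {
    px <- rep(rx0[m]:rx1[m], times = ry1[m] - ry0[m] + 1L)
    py <- rep(ry0[m]:ry1[m], each = rx1[m] - rx0[m] + 1L)
    hit[m] <- any(dist_point_seg(px, py, x1, y1, x2, y2) <= buffer)
  }
  covered[idx[hit]] <- TRUE
  covered
}

# Coverage of the lung tile set by the polyline through (x, y), dilated by
# `buffer`. Returns the covered lung-tile count, the lung-tile count, and
# the covered logical vector (for incremental reuse by the generator).
coverage_from_tiles <- function(x, y, tiles, buffer) {
  lung <- tiles$lung
  n_lung <- sum(lung)
  assert_that(n_lung > 0, "mask contains no lung tiles", "cadgaze_undefined")
  covered <- rep(FALSE, nrow(tiles))
  n <- length(x)
  if (n >= 1) {
    if (n == 1) {
      covered <- cover_segment(covered, lung, x, y, x, y, tiles, buffer)
    } else {
      for (s in seq_len(n - 1L)) {
        covered <- cover_segment(covered, lung, x[s], y[s], x[s + 1L],
                                 y[s + 1L], tiles, buffer)
      }
    }
  }
  list(n_covered = sum(covered & lung), n_lung = n_lung, covered = covered)
}
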