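# Diagnostic rendering of a gaze recording: lung mask tint, gaze polyline
# shaded from dark (start) to light (end), and the buffered band around the
# path coloured by overlap density. Purely visual; no numeric contract
# beyond the output dimensions.

#' Render a gaze overlay raster
#'
#' Produces an RGB raster (values in \[0, 1\]) the size of the input image:
#' the lung mask is tinted cyan, the buffered band around the gaze path is
#' drawn in orange deepening to red with overlap density, and the polyline
#' itself is shaded from black (start) to white (end). Deterministic for a
#' fixed input. An empty recording yields the mask-only image.
#'
#' @param rec A [gaze_recording()].
#' @param mask Logical lung mask matrix matching the recording's image.
#' @param buffer Band radius around the path in pixels.
#' @return A numeric array `height` x `width` x 3.
#' @export
render_overlay <- function(rec, mask, buffer = 50) {
  assert_that(nrow(mask) == rec$image_height && ncol(mask) == rec$image_width,
              "mask dimensions must match the recording's image",
              "cadgaze_input")
  h <- rec$image_height
  w <- rec$image_width
  img <- array(0.12, dim = c(h, w, 3))
  # mask tint (cyan)
  img[, , 2][mask] <- 0.45
  img[, , 3][mask] <- 0.5
  s <- rec$samples[rec$samples$valid, ]
  n <- nrow(s)
  if (n == 0) return(img)
  # overlap density of the buffered band, accumulated per segment over its
  # local bounding window
  density <- matrix(0L, h, w)
  segs <- max(1L, n - 1L)
  for (i in seq_len(segs)) {
    x1 <- s$x[i]; y1 <- s$y[i]
    x2 <- s$x[min(i + 1L, n)]; y2 <- s$y[min(i + 1L, n)]
    cx0 <- max(0L, floor(min(x1, x2) - buffer))
    cx1 <- min(w - 1L, ceiling(max(x1, x2) + buffer))
    cy0 <- max(0L, floor(min(y1, y2) - buffer))
    cy1 <- min(h - 1L, ceiling(max(y1, y2) + buffer))
    if (cx1 < cx0 || cy1 < cy0) next
    px <- rep(cx0:cx1, times = cy1 - cy0 + 1L)
    py <- rep(cy0:cy1, each = cx1 - cx0 + 1L)
    hit <- dist_point_seg(px, py, x1, y1, x2, y2) <= buffer
    idx <- cbind(py[hit] + 1L, px[hit] + 1L)
    density[idx] <- density[idx] + 1L
  }
  band <- density > 0
  dens <- density / max(density)
  # orange (1, 0.6, 0) deepening to red (0.8, 0, 0)
  img[, , 1][band] <- 1 - 0.2 * dens[band]
  img[, , 2][band] <- 0.6 * (1 - dens[band])
  img[, , 3][band] <- 0
  # polyline shaded start -> end
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      len <- max(1, ceiling(sqrt((s$x[i + 1] - s$x[i])^2 +
                                   (s$y[i + 1] - s$y[i])^2) * 2))
      tt <- seq(0, 1, length.out = len + 1)
      px <- round(s$x[i] + tt * (s$x[i + 1] - s$x[i]))
      py <- round(s$y[i] + tt * (s$y[i + 1] - s$y[i]))
      keep <- px >= 0 & px < w & py >= 0 & py < h
      shade <- (i - 1 + tt) / (n - 1)
      idx <- cbind(py[keep] + 1L, px[keep] + 1L)
      for (ch in 1:3) img[, , ch][idx] <- shade[keep]
    }
  } else {
    px <- round(s$x[1]); py <- round(s$y[1])
    if (px >= 0 && px < w && py >= 0 && py < h) {
      img[py + 1L, px + 1L, ] <- 0
    }
  }
  img
}

#' Plot a gaze recording over its lung mask
#'
#' ggplot companion to [render_overlay()]: lung outline as a filled tile
#' layer (downsampled for large images), the gaze path coloured by time,
#' and optionally the lesion AOI rectangle.
#'
#' @param rec A [gaze_recording()].
#' @param mask Logical lung mask matrix.
#' @param aoi Optional [lesion_aoi()] to outline.
#' @param downsample Keep every `downsample`-th mask pixel in the tile
#'   layer.
#' @return A ggplot.
#' @export
plot_gaze_overlay <- function(rec, mask, aoi = NULL, downsample = 8L) {
  ys <- seq(1L, nrow(mask), by = downsample)
  xs <- seq(1L, ncol(mask), by = downsample)
  grid <- expand.grid(x = xs - 1L, y = ys - 1L)
  grid$lung <- as.vector(t(mask[ys, xs, drop = FALSE]))
  s <- rec$samples[rec$samples$valid, ]
  p <- ggplot2::ggplot() +
    ggplot2::geom_tile(
      data = grid[grid$lung, ],
      ggplot2::aes(x = .data$x, y = .data$y),
      width = downsample, height = downsample, fill = "#9adfe0",
      alpha = 0.6
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  if (nrow(s) > 0) {
    p <- p + ggplot2::geom_path(
      data = s, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$t),
      linewidth = 0.4
    ) +
      ggplot2::scale_colour_gradient(low = "black", high = "white",
                                     name = "t (s)")
  }
  if (!is.null(aoi)) {
    p <- p + ggplot2::annotate("rect", xmin = aoi$x_min, xmax = aoi$x_max,
                               ymin = aoi$y_min, ymax = aoi$y_max,
                               fill = NA, colour = "red")
  }
  p
}
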