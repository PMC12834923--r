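# Synthetic lung-field masks and box placement. A mask is a logical matrix
# (height x width, mask[y + 1, x + 1]) with two disjoint elliptical "lung"
# regions. Real studies obtain lung fields from a segmentation model; here
# the mask is a geometric stand-in with a controlled area fraction.

#' Generate a synthetic binary lung-field mask
#'
#' Draws two disjoint, axis-aligned elliptical lung regions centred left and
#' right of the image midline. The combined area fraction is drawn uniformly
#' from `area_range` and realised exactly up to rasterisation. Deterministic
#' for a fixed seed.
#'
#' @param width,height Image dimensions in pixels (both at least 64).
#' @param seed Integer seed.
#' @param area_range Length-2 numeric; bounds for the combined lung area as
#'   a fraction of the frame. Must lie within \[0.25, 0.45\].
#' @return A logical matrix of dimension `height` x `width`, with the
#'   ellipse parameters attached as attribute `params`.
#' @export
make_lung_mask <- function(width, height, seed = 1L,
                           area_range = c(0.25, 0.29)) {
  assert_that(is_count(width) && is_count(height) && width >= 64 &&
                height >= 64,
              "`width` and `height` must be integers >= 64", "cadgaze_config")
  assert_that(length(area_range) == 2 && area_range[1] >= 0.25 &&
                area_range[2] <= 0.45 && area_range[1] <= area_range[2],
              "`area_range` must lie within [0.25, 0.45]", "cadgaze_config")
  params <- withr::with_seed(seed, {
    frac <- stats::runif(1, area_range[1], area_range[2])
    b <- height * stats::runif(1, 0.33, 0.38)      # semi-axis, vertical
    a <- frac * width * height / (2 * pi * b)      # semi-axis, horizontal
    # keep both ellipses inside the frame with a central gap
    gap <- width * stats::runif(1, 0.015, 0.03)
    a <- min(a, (width / 2 - gap) / 2 - 2)
    cy <- height * stats::runif(1, 0.48, 0.52)
    b <- min(b, cy - 1, height - cy - 1)
    list(cx = c(width / 2 - gap - a, width / 2 + gap + a),
         cy = c(cy, cy), a = a, b = b)
  })
  x <- matrix((seq_len(width) - 1), nrow = height, ncol = width, byrow = TRUE)
  y <- matrix((seq_len(height) - 1), nrow = height, ncol = width)
  mask <- matrix(FALSE, height, width)
  for (k in 1:2) {
    mask <- mask | (((x - params$cx[k]) / params$a)^2 +
                      ((y - params$cy[k]) / params$b)^2 <= 1)
  }
  attr(mask, "params") <- params
  mask
}

#' Sample a box centred inside a lung mask
#'
#' Draws a pixel box whose centre pixel lies inside the mask, with side
#' lengths drawn uniformly from `size_range`. Box coordinates are half-open
#' pixel intervals clipped to the image. Uses the current RNG state.
#'
#' @param mask Logical lung mask matrix.
#' @param size_range Length-2 numeric; min and max side length in pixels.
#' @param avoid Optional box (named vector/list with `x_min`, `y_min`,
#'   `x_max`, `y_max`): the sampled box must not intersect `avoid` expanded
#'   by `avoid_margin` on all sides (used to keep false prompts off the
#'   lesion AOI). Placement is retried up to `max_tries` times.
#' @param avoid_margin Expansion of `avoid` in pixels.
#' @param max_tries Bounded number of placement attempts.
#' @return A named numeric vector `c(x_min, y_min, x_max, y_max)`.
#' @export
sample_lesion_box <- function(mask, size_range = c(40, 160), avoid = NULL,
                              avoid_margin = 50, max_tries = 200L) {
  inside <- which(mask)
  assert_that(length(inside) > 0, "mask is empty: cannot place a box",
              "cadgaze_placement")
  height <- nrow(mask)
  width <- ncol(mask)
  for (try in seq_len(max_tries)) {
    pick <- inside[sample.int(length(inside), 1L)]
    cy <- (pick - 1L) %% height
    cx <- (pick - 1L) %/% height
    w <- round(stats::runif(1, size_range[1], size_range[2]))
    h <- round(stats::runif(1, size_range[1], size_range[2]))
    x_min <- clamp(round(cx - w / 2), 0, max(0, width - w))
    y_min <- clamp(round(cy - h / 2), 0, max(0, height - h))
    box <- c(x_min = x_min, y_min = y_min,
             x_max = min(x_min + w, width), y_max = min(y_min + h, height))
    if (!is.null(avoid)) {
      sep <- box[["x_max"]] <= avoid[["x_min"]] - avoid_margin ||
        box[["x_min"]] >= avoid[["x_max"]] + avoid_margin ||
        box[["y_max"]] <= avoid[["y_min"]] - avoid_margin ||
        box[["y_min"]] >= avoid[["y_max"]] + avoid_margin
      if (!sep) next
    }
    return(box)
  }
  stop_cadgaze("could not place a box after bounded retries",
               "cadgaze_placement")
}
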