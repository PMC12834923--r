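# Independent brute-force oracles and small fixture builders shared across
# the test files. The oracles deliberately use the most literal computation
# available (per-sample loops, per-pixel rasterisation) and never call the
# implementation paths they check.

# recording with explicit samples
make_rec <- function(x, y, valid = TRUE, rate = 60, duration = NULL,
                     width = 300, height = 300) {
  n <- length(x)
  valid <- rep_len(valid, n)
  gaze_recording(tibble::tibble(t = (seq_len(n) - 1) / rate, x = x, y = y,
                                valid = valid),
                 sampling_rate = rate, duration = duration,
                 image_width = width, image_height = height)
}

# dwell oracle: per-sample membership loop against the expanded box
oracle_dwell <- function(rec, box, margin) {
  count <- 0
  for (i in seq_len(nrow(rec$samples))) {
    s <- rec$samples[i, ]
    if (!s$valid) next
    inside <- s$x >= max(0, box[["x_min"]] - margin) &&
      s$x <= min(rec$image_width, box[["x_max"]] + margin) &&
      s$y >= max(0, box[["y_min"]] - margin) &&
      s$y <= min(rec$image_height, box[["y_max"]] + margin)
    if (inside) count <- count + 1
  }
  count / rec$sampling_rate
}

# path oracle: explicit pairwise distance summation over valid samples
oracle_path <- function(rec) {
  s <- rec$samples[rec$samples$valid, ]
  if (nrow(s) < 2) return(0)
  total <- 0
  for (i in 2:nrow(s)) {
    total <- total + sqrt((s$x[i] - s$x[i - 1])^2 + (s$y[i] - s$y[i - 1])^2)
  }
  total
}

# coverage oracle: rasterise the buffered polyline per pixel, then test
# tile intersection with the centre-pixel lung rule
oracle_coverage <- function(rec, mask, cell, buffer) {
  h <- nrow(mask); w <- ncol(mask)
  s <- rec$samples[rec$samples$valid, ]
  n <- nrow(s)
  if (n < 1) return(0)
  px <- rep(0:(w - 1), each = h)
  py <- rep(0:(h - 1), times = w)
  dmin <- rep(Inf, length(px))
  segs <- if (n == 1) list(c(1, 1)) else
    lapply(seq_len(n - 1), function(i) c(i, i + 1))
  for (sg in segs) {
    d <- cadgaze:::dist_point_seg(px, py, s$x[sg[1]], s$y[sg[1]],
                                  s$x[sg[2]], s$y[sg[2]])
    dmin <- pmin(dmin, d)
  }
  covpix <- dmin <= buffer  # indexed [x * h + y + 1]
  nx <- ceiling(w / cell); ny <- ceiling(h / cell)
  lung <- 0; covd <- 0
  for (i in 0:(ny - 1)) for (j in 0:(nx - 1)) {
    cx <- j * cell + floor(cell / 2)
    cy <- i * cell + floor(cell / 2)
    if (cx >= w || cy >= h) next
    if (!mask[cy + 1, cx + 1]) next
    lung <- lung + 1
    xs <- (j * cell):(min((j + 1) * cell, w) - 1)
    ys <- (i * cell):(min((i + 1) * cell, h) - 1)
    hit <- FALSE
    for (xx in xs) {
      if (any(covpix[xx * h + ys + 1])) { hit <- TRUE; break }
    }
    if (hit) covd <- covd + 1
  }
  covd / lung
}

# two-pass connected-component count for binary matrices (4-connectivity)
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (!mask[r, c]) next
    up <- if (r > 1 && mask[r - 1, c]) lab[r - 1, c] else 0L
    left <- if (c > 1 && mask[r, c - 1]) lab[r, c - 1] else 0L
    if (up == 0L && left == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[r, c] <- nxt
    } else if (up > 0L && left > 0L) {
      ru <- find(up); rl <- find(left)
      parent[max(ru, rl)] <- min(ru, rl)
      lab[r, c] <- min(ru, rl)
    } else {
      lab[r, c] <- max(up, left)
    }
  }
  roots <- unique(vapply(seq_len(nxt), find, integer(1)))
  length(roots)
}

# small random mask with guaranteed lung tiles (for metric property tests)
random_blob_mask <- function(w, h, p = 0.5) {
  matrix(stats::runif(w * h) < p, h, w)
}

# tiny two-reader generator config for fast end-to-end tests
small_config <- function(seed = 1L, n_tp = 4, n_fn = 1, n_fnfp = 1,
                         n_tn = 2, n_fp = 1, readers = NULL,
                         effects = condition_effects()) {
  if (is.null(readers)) {
    readers <- dplyr::bind_rows(
      reader_profile("A", 3, 0.5, 0.8, 1500, 0.5, dropout_rate = 0.05),
      reader_profile("B", 4, 0.7, 1.0, 2000, 0.6, dropout_rate = 0.1)
    )
  }
  generator_config(
    readers = readers, effects = effects,
    design = design_config(n_tp, n_fn, n_fnfp, n_tn, n_fp),
    image_width = 640, image_height = 360,
    lesion_size_range = c(30, 80), seed = seed
  )
}
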