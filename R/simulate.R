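# Synthetic reader-study generator. The generator targets the five gaze
# metrics directly rather than modelling oculomotor physiology: per read it
# draws latent metric targets (log-normal multipliers around reader-specific
# medians, additive condition shifts when a prompt is displayed) and then
# constructs a 60 Hz sample stream that realises them -- a serpentine
# sequence of fixation stamps over the lung tile grid for coverage, a
# scheduled lesion visit for dwell and time to first fixation, and
# within-fixation jitter whose amplitude fills the gaze-path-length budget.
# Samples are independently marked invalid with the reader's dropout rate;
# dropped samples are emitted (validity FALSE), preserving the
# expected-sample denominator of the capture ratio.

METRIC_NAMES <- c("time", "dwell", "ttff", "path", "coverage")

#' Reader profile for the synthetic generator
#'
#' Baseline (no-prompt) behaviour of one reader: per-metric medians, the
#' sample dropout rate of the tracker for this reader, the reader's
#' unassisted decision operating point, and the prompt-adoption propensity.
#'
#' @param reader_id Identifier.
#' @param time_s,dwell_s,ttff_s Median interpretation time, lesion dwell
#'   time and time to first fixation, in seconds (all positive).
#' @param path_px Median gaze-path length in pixels.
#' @param coverage Median lung-field coverage fraction in (0, 1\].
#' @param dropout_rate Per-sample probability of a dropped (invalid) sample,
#'   in \[0, 1).
#' @param decision_sensitivity,decision_specificity Probability of a
#'   correct positive / negative call when deciding unaided.
#' @param adoption Probability that a session-1 decision simply follows the
#'   displayed prompt (positive when a box is shown, negative when not).
#' @return A one-row tibble.
#' @export
reader_profile <- function(reader_id, time_s, dwell_s, ttff_s, path_px,
                           coverage, dropout_rate = 0.1,
                           decision_sensitivity = 0.7,
                           decision_specificity = 0.9, adoption = 0.8) {
  assert_that(all(c(time_s, dwell_s, ttff_s, path_px) > 0),
              "metric medians must be positive", "cadgaze_config")
  assert_that(coverage > 0 && coverage <= 1,
              "`coverage` median must lie in (0, 1]", "cadgaze_config")
  assert_that(dropout_rate >= 0 && dropout_rate < 1,
              "`dropout_rate` must lie in [0, 1)", "cadgaze_config")
  tibble::tibble(reader_id = as.character(reader_id), time_s = time_s,
                 dwell_s = dwell_s, ttff_s = ttff_s, path_px = path_px,
                 coverage = coverage, dropout_rate = dropout_rate,
                 decision_sensitivity = decision_sensitivity,
                 decision_specificity = decision_specificity,
                 adoption = adoption)
}

#' Condition effects applied when a prompt is displayed
#'
#' Additive shifts of the latent metric targets under the with-prompt
#' condition, on each metric's natural scale. Negative `d_ttff_s` means the
#' lesion is found faster. Dwell and time-to-first-fixation shifts apply
#' only when the displayed box marks the lesion (TP cases); the global
#' search shifts (time, path, coverage) apply whenever any box is shown.
#'
#' @param d_time_s,d_dwell_s,d_ttff_s Shifts in seconds.
#' @param d_path_px Shift in pixels.
#' @param d_coverage Shift of the coverage fraction (e.g. 0.105 for 10.5
#'   percentage points).
#' @return A list of class `condition_effects`.
#' @export
condition_effects <- function(d_time_s = 4.9, d_dwell_s = 1.3,
                              d_ttff_s = -1.3, d_path_px = 2076,
                              d_coverage = 0.105) {
  structure(list(d_time_s = d_time_s, d_dwell_s = d_dwell_s,
                 d_ttff_s = d_ttff_s, d_path_px = d_path_px,
                 d_coverage = d_coverage),
            class = "condition_effects")
}

#' Generator configuration
#'
#' Bundles everything [simulate_study()] needs: reader profiles, condition
#' effects, the case-allocation design, display geometry, sampling rate,
#' per-metric dispersion, and the seed.
#'
#' @param readers Tibble of [reader_profile()] rows (at least one).
#' @param effects A [condition_effects()].
#' @param design A [design_config()].
#' @param image_width,image_height Display raster dimensions in pixels.
#' @param sampling_rate Gaze sampling rate in Hz.
#' @param dispersion Named numeric: log-scale standard deviation of the
#'   per-read log-normal multiplier for each metric (names `time`, `dwell`,
#'   `ttff`, `path`, `coverage`).
#' @param rho2 Share of the squared dispersion attributed to a case-level
#'   random factor shared by all reads of a case (the rest is read-level
#'   noise).
#' @param lesion_size_range Side-length range (pixels) for lesion and
#'   false-prompt boxes.
#' @param mask_area_range Lung area fraction range passed to
#'   [make_lung_mask()].
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(readers, effects = condition_effects(),
                             design = design_config(),
                             image_width = 2560, image_height = 1440,
                             sampling_rate = 60,
                             dispersion = c(time = 0.30, dwell = 0.35,
                                            ttff = 0.40, path = 0.30,
                                            coverage = 0.15),
                             rho2 = 0.5,
                             lesion_size_range = c(40, 160),
                             mask_area_range = c(0.25, 0.29), seed = 1L) {
  assert_that(nrow(readers) >= 1, "at least one reader profile is required",
              "cadgaze_config")
  assert_that(all(METRIC_NAMES %in% names(dispersion)),
              "`dispersion` must name all five metrics", "cadgaze_config")
  assert_that(is_number(sampling_rate) && sampling_rate > 0,
              "`sampling_rate` must be positive", "cadgaze_config")
  assert_that(rho2 >= 0 && rho2 <= 1, "`rho2` must lie in [0, 1]",
              "cadgaze_config")
  structure(list(readers = readers, effects = effects, design = design,
                 image_width = image_width, image_height = image_height,
                 sampling_rate = sampling_rate,
                 dispersion = dispersion[METRIC_NAMES], rho2 = rho2,
                 lesion_size_range = lesion_size_range,
                 mask_area_range = mask_area_range, seed = as.integer(seed)),
            class = "generator_config")
}

#' Calibrated three-reader study configuration
#'
#' The bundled default configuration reproduces the conditions of a
#' three-reader crossover chest-radiograph study with an 80%/80% display
#' operating point over 180 cases (96 TP): reader baselines are the
#' observed without-prompt (session 2) metric medians, decision operating
#' points are the session-2 sensitivities/specificities, adoption rates are
#' the observed total prompt-concordance rates, and the condition effects
#' are the study-level mixed-model contrasts (+4.9 s interpretation time,
#' +1.3 s dwell, -1.3 s time to first fixation, +2076 px path, +10.5
#' percentage points coverage).
#'
#' @param seed Integer seed.
#' @return A [generator_config()].
#' @export
default_generator_config <- function(seed = 1L) {
  readers <- dplyr::bind_rows(
    reader_profile("R1", time_s = 10.2, dwell_s = 1.2, ttff_s = 1.9,
                   path_px = 5706, coverage = 0.680, dropout_rate = 0.12,
                   decision_sensitivity = 0.675, decision_specificity = 0.950,
                   adoption = 0.71),
    reader_profile("R2", time_s = 4.4, dwell_s = 0.4, ttff_s = 2.7,
                   path_px = 2308, coverage = 0.468, dropout_rate = 0.08,
                   decision_sensitivity = 0.792, decision_specificity = 0.633,
                   adoption = 0.95),
    reader_profile("R3", time_s = 8.6, dwell_s = 1.3, ttff_s = 1.4,
                   path_px = 4782, coverage = 0.624, dropout_rate = 0.04,
                   decision_sensitivity = 0.600, decision_specificity = 0.967,
                   adoption = 0.77)
  )
  generator_config(readers = readers, seed = seed)
}

# serpentine visiting order over stamp tiles: one lung at a time (split at
# the image midline), rows in reading order within the first lung and back
# through the second, alternating x direction row by row
serpentine_order <- function(pool, tiles, cell, width, left_first = TRUE,
                             top_down = TRUE) {
  left <- tiles$cx[pool] < width / 2
  halves <- if (left_first) list(pool[left], pool[!left]) else
    list(pool[!left], pool[left])
  out <- integer(0)
  xdir <- TRUE
  for (h in seq_along(halves)) {
    idx <- halves[[h]]
    if (length(idx) == 0L) next
    rb <- tiles$y0[idx] / cell
    down <- if (h == 1L) top_down else !top_down
    for (r in sort(unique(rb), decreasing = !down)) {
      sel <- idx[rb == r]
      sel <- sel[order(tiles$cx[sel], decreasing = !xdir)]
      out <- c(out, sel)
      xdir <- !xdir
    }
  }
  out
}

# One latent draw per metric for one read. Read-level noise is a log-normal
# multiplier around the reader's (shifted) median; the case-level factor
# `case_z` enters as an additive intercept on a common scale (`pool`, the
# across-reader median), matching the additive crossed-intercept structure
# of the analysis model -- a reader-scaled multiplicative case factor would
# induce an unmodelled reader-by-case interaction.
draw_metric_latents <- function(profile, effects, with_bb, on_lesion,
                                case_z, dispersion, rho2, pool = NULL) {
  if (is.null(pool)) {
    pool <- list(time = profile$time_s, dwell = profile$dwell_s,
                 ttff = profile$ttff_s, path = profile$path_px,
                 coverage = profile$coverage)
  }
  read_mult <- function(metric) {
    exp(dispersion[[metric]] * sqrt(1 - rho2) * stats::rnorm(1))
  }
  case_eff <- function(metric) {
    pool[[metric]] * dispersion[[metric]] * sqrt(rho2) * case_z[[metric]]
  }
  ib <- as.numeric(with_bb)
  il <- as.numeric(with_bb && on_lesion)
  list(
    time = max((profile$time_s + ib * effects$d_time_s) * read_mult("time") +
                 case_eff("time"), 1),
    dwell = max((profile$dwell_s + il * effects$d_dwell_s) *
                  read_mult("dwell") + case_eff("dwell"), 0.02),
    ttff = max((profile$ttff_s + il * effects$d_ttff_s) *
                 read_mult("ttff") + case_eff("ttff"), 0.02),
    path = max((profile$path_px + ib * effects$d_path_px) *
                 read_mult("path") + case_eff("path"), 0),
    coverage = clamp((profile$coverage + ib * effects$d_coverage) *
                       read_mult("coverage") + case_eff("coverage"),
                     0.02, 0.97)
  )
}

# across-reader median scale used for the additive case intercepts
pooled_baselines <- function(readers) {
  list(time = mean(readers$time_s), dwell = mean(readers$dwell_s),
       ttff = mean(readers$ttff_s), path = mean(readers$path_px),
       coverage = mean(readers$coverage))
}

#' Simulate one gaze recording
#'
#' Generates the 60 Hz sample stream for one read of one case under one
#' condition. The read duration, lesion visit (latency and dwell), path
#' length and lung coverage are drawn as latent targets from the reader
#' profile plus condition effects and then realised by construction; the
#' latent targets are returned alongside the recording for recovery
#' testing. Draws from the current RNG state.
#'
#' @param case One row of a case table with boxes and image dimensions
#'   filled in.
#' @param condition `"with_bb"` or `"without_bb"`.
#' @param profile One [reader_profile()] row.
#' @param effects A [condition_effects()].
#' @param tiles [grid_tiles()] table for the case's lung mask.
#' @param sampling_rate Hz.
#' @param margin,buffer AOI margin and path buffer in pixels (the study
#'   constants; used to keep search fixations off the lesion AOI and to
#'   plan tile coverage).
#' @param dispersion,rho2 As in [generator_config()].
#' @param case_z Optional named per-metric case factors (standard normal);
#'   defaults to zeros.
#' @param pool Optional named list of across-reader baseline medians (see
#'   [generator_config()]'s `rho2`): the scale of the additive case
#'   intercepts. Defaults to the profile's own medians.
#' @return A list with elements `recording` (a [gaze_recording()]) and
#'   `latent` (a one-row tibble of the drawn targets plus a `clamped`
#'   flag).
#' @export
simulate_scanpath <- function(case, condition = c("with_bb", "without_bb"),
                              profile, effects, tiles, sampling_rate = 60,
                              margin = 50, buffer = 50,
                              dispersion = c(time = 0.30, dwell = 0.35,
                                             ttff = 0.40, path = 0.30,
                                             coverage = 0.15),
                              rho2 = 0.5, case_z = NULL, pool = NULL) {
  condition <- match.arg(condition)
  if (is.null(case_z)) {
    case_z <- stats::setNames(as.list(rep(0, 5)), METRIC_NAMES)
  }
  with_bb <- condition == "with_bb"
  has_lesion <- isTRUE(case$lesion_present) && !is.na(case$lesion_x_min)
  on_lesion <- has_lesion && isTRUE(as.character(case$group) == "TP")
  width <- attr(tiles, "width")
  height <- attr(tiles, "height")
  cell <- attr(tiles, "cell")
  rate <- sampling_rate
  d <- profile$dropout_rate

  lat <- draw_metric_latents(profile, effects, with_bb, on_lesion, case_z,
                             dispersion, rho2, pool)
  dur <- lat$time
  n <- max(4L, round(dur * rate))
  clamped <- FALSE

  # -- lesion visit schedule ------------------------------------------------
  i_les <- m_les <- 0L
  aoi <- NULL
  if (has_lesion) {
    box <- c(x_min = case$lesion_x_min, y_min = case$lesion_y_min,
             x_max = case$lesion_x_max, y_max = case$lesion_y_max)
    aoi <- lesion_aoi(box, margin, width, height)
    i_want <- max(1L, round(lat$ttff * rate))
    i_les <- min(i_want, max(1L, floor(0.6 * n)))
    m_want <- max(1L, round(lat$dwell * rate / (1 - d)))
    m_les <- min(m_want, floor(0.8 * n), n - i_les - 2L)
    m_les <- max(m_les, 1L)
    if (abs(i_les - i_want) > 2L || abs(m_les - m_want) > 2L) clamped <- TRUE
  }

  # -- coverage plan: serpentine fixation stamps over the lung grid ---------
  lung <- tiles$lung
  n_lung <- sum(lung)
  assert_that(n_lung > 0, "case mask has no lung tiles", "cadgaze_undefined")
  k_target <- max(1L, round(lat$coverage * n_lung))
  eligible <- lung
  if (has_lesion) {
    pad <- 3 * 12 + 10  # keep search fixations clear of the AOI
    eligible <- eligible & !(tiles$cx >= aoi$x_min - pad &
                               tiles$cx <= aoi$x_max + pad &
                               tiles$cy >= aoi$y_min - pad &
                               tiles$cy <= aoi$y_max + pad)
  }
  covered <- rep(FALSE, nrow(tiles))
  if (has_lesion) {
    lx <- (case$lesion_x_min + case$lesion_x_max) / 2
    ly <- (case$lesion_y_min + case$lesion_y_max) / 2
    covered <- cover_segment(covered, lung, lx, ly, lx, ly, tiles, buffer)
  }

  ox <- sample.int(3L, 1L) - 1L
  oy <- sample.int(3L, 1L) - 1L
  pool <- which(eligible &
                  ((tiles$x0 / cell) %% 3 == ox) &
                  ((tiles$y0 / cell) %% 3 == oy))
  if (length(pool) > 0) {
    # serpentine tour per lung (left lung then right or vice versa, top-down
    # or bottom-up); among the four variants pick the one whose stamp at the
    # scheduled lesion-visit time lies nearest the lesion, so the detour to
    # the prompt costs little path
    orders <- lapply(1:4, function(v) {
      serpentine_order(pool, tiles, cell, width,
                       left_first = v <= 2, top_down = v %% 2 == 1)
    })
    pick <- sample.int(4L, 1L)
    if (has_lesion) {
      f_est <- max(1L, min(ceiling(k_target / 7.5), length(pool)))
      frac <- i_les / n
      dists <- vapply(orders, function(o) {
        j <- clamp(round(frac * f_est), 1, f_est)
        sqrt((tiles$cx[o[j]] - (case$lesion_x_min + case$lesion_x_max) / 2)^2 +
               (tiles$cy[o[j]] - (case$lesion_y_min + case$lesion_y_max) / 2)^2)
      }, numeric(1))
      pick <- which.min(dists)
    }
    pool <- orders[[pick]]
  }
  tx <- ty <- numeric(0)
  n_cov <- sum(covered & lung)
  pos <- NULL
  for (p in pool) {
    if (n_cov >= k_target) break
    nx_t <- tiles$cx[p]
    ny_t <- tiles$cy[p]
    if (is.null(pos)) {
      covered <- cover_segment(covered, lung, nx_t, ny_t, nx_t, ny_t, tiles,
                               buffer)
    } else {
      covered <- cover_segment(covered, lung, pos[1], pos[2], nx_t, ny_t,
                               tiles, buffer)
    }
    pos <- c(nx_t, ny_t)
    tx <- c(tx, nx_t)
    ty <- c(ty, ny_t)
    n_cov <- sum(covered & lung)
  }
  # fill remaining pockets greedily (nearest uncovered eligible tile)
  while (n_cov < k_target) {
    open <- which(eligible & !covered)
    if (length(open) == 0L) { clamped <- TRUE; break }
    if (is.null(pos)) pos <- c(tiles$cx[open[1]], tiles$cy[open[1]])
    dd <- (tiles$cx[open] - pos[1])^2 + (tiles$cy[open] - pos[2])^2
    p <- open[which.min(dd)]
    covered <- cover_segment(covered, lung, pos[1], pos[2], tiles$cx[p],
                             tiles$cy[p], tiles, buffer)
    pos <- c(tiles$cx[p], tiles$cy[p])
    tx <- c(tx, tiles$cx[p])
    ty <- c(ty, tiles$cy[p])
    n_cov <- sum(covered & lung)
  }
  if (length(tx) == 0L) {  # degenerate: single fixation somewhere in lung
    p <- which(lung)[1L]
    tx <- tiles$cx[p]
    ty <- tiles$cy[p]
  }

  # -- temporal allocation --------------------------------------------------
  # all search time is spread over the planned fixations: leftover reading
  # time lengthens fixations instead of adding travel, so interpretation
  # time does not leak into path length
  m_search <- n - m_les
  f_a <- length(tx)
  if (f_a * 2L > m_search) {
    f_a <- max(1L, floor(m_search / 2))
    tx <- tx[seq_len(f_a)]
    ty <- ty[seq_len(f_a)]
    clamped <- TRUE
  }
  q_a <- floor(m_search / f_a)
  lens <- rep(q_a, f_a)
  extra <- m_search - q_a * f_a
  if (extra > 0L) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L

  # insert the lesion visit at its slot, splitting the spanning fixation
  fx <- tx; fy <- ty; fl <- lens
  is_les <- rep(FALSE, length(fl))
  if (has_lesion && m_les > 0L) {
    cum <- cumsum(fl)
    at <- which(cum > i_les)[1]
    before <- if (at > 1) cum[at - 1] else 0L
    len1 <- i_les - before
    len2 <- fl[at] - len1
    fx <- append(fx, (case$lesion_x_min + case$lesion_x_max) / 2, after = at)
    fy <- append(fy, (case$lesion_y_min + case$lesion_y_max) / 2, after = at)
    fl <- append(fl, m_les, after = at)
    is_les <- append(is_les, TRUE, after = at)
    fl[at] <- len1
    if (len2 > 0L) {
      fx <- append(fx, fx[at], after = at + 1L)
      fy <- append(fy, fy[at], after = at + 1L)
      fl <- append(fl, len2, after = at + 1L)
      is_les <- append(is_les, FALSE, after = at + 1L)
    }
    keep <- fl > 0L
    fx <- fx[keep]; fy <- fy[keep]; fl <- fl[keep]; is_les <- is_les[keep]
  }

  # -- jitter amplitude from the path budget --------------------------------
  n_fix <- length(fl)
  hops <- if (n_fix > 1) sum(sqrt(diff(fx)^2 + diff(fy)^2)) else 0
  n_eff <- max(1, (1 - d) * n - n_fix)
  sigma <- (lat$path - hops) / (n_eff * sqrt(pi))
  if (!is.finite(sigma) || sigma < 0.3 || sigma > 12) {
    sigma <- clamp(sigma, 0.3, 12)
    clamped <- TRUE
  }

  # -- emit samples ---------------------------------------------------------
  x <- rep(fx, fl) + stats::rnorm(n, 0, sigma)
  y <- rep(fy, fl) + stats::rnorm(n, 0, sigma)
  les_slot <- rep(is_les, fl)
  if (has_lesion) {
    if (any(les_slot)) {
      bw <- case$lesion_x_max - case$lesion_x_min
      bh <- case$lesion_y_max - case$lesion_y_min
      sig_l <- max(0.3, min(sigma, 8, bw / 4, bh / 4))
      nl <- sum(les_slot)
      x[les_slot] <- clamp(fx[is_les][1] + stats::rnorm(nl, 0, sig_l),
                           aoi$x_min + 0.5, aoi$x_max - 0.5)
      y[les_slot] <- clamp(fy[is_les][1] + stats::rnorm(nl, 0, sig_l),
                           aoi$y_min + 0.5, aoi$y_max - 0.5)
    }
    # search samples must stay out of the AOI so dwell and first entry are
    # exactly the scheduled visit
    bad <- which(!les_slot & in_aoi(x, y, aoi))
    for (b in bad) {
      push <- c(aoi$x_min - 1 - x[b], x[b] - (aoi$x_max + 1),
                aoi$y_min - 1 - y[b], y[b] - (aoi$y_max + 1))
      side <- which.max(push)
      if (side == 1) x[b] <- aoi$x_min - stats::runif(1, 1, 8)
      if (side == 2) x[b] <- aoi$x_max + stats::runif(1, 1, 8)
      if (side == 3) y[b] <- aoi$y_min - stats::runif(1, 1, 8)
      if (side == 4) y[b] <- aoi$y_max + stats::runif(1, 1, 8)
    }
  }
  x <- clamp(x, 0, width - 1)
  y <- clamp(y, 0, height - 1)
  valid <- stats::runif(n) >= d
  samples <- tibble::tibble(t = (seq_len(n) - 1L) / rate, x = x, y = y,
                            valid = valid)
  rec <- gaze_recording(samples, sampling_rate = rate, duration = dur,
                        image_width = width, image_height = height)
  latent <- tibble::tibble(
    condition = condition,
    latent_time_s = dur,
    latent_dwell_s = if (has_lesion) lat$dwell else NA_real_,
    latent_ttff_s = if (has_lesion) lat$ttff else NA_real_,
    latent_path_px = lat$path,
    latent_coverage = lat$coverage,
    clamped = clamped
  )
  list(recording = rec, latent = latent)
}

# one binary decision for one read
decide_read <- function(profile, lesion_present, displayed, session) {
  if (session == 1L && stats::runif(1) < profile$adoption) {
    return(if (displayed) "positive" else "negative")
  }
  p_pos <- if (lesion_present) profile$decision_sensitivity else
    1 - profile$decision_specificity
  if (stats::runif(1) < p_pos) "positive" else "negative"
}

#' Simulate a complete crossover reader study
#'
#' Generates the full dataset bundle: case allocation with lesion and
#' prompt boxes placed on synthetic lung masks, one gaze recording per
#' reader x session x case (session 1 shows the prompt where the design
#' displays one; session 2 is always unprompted), binary decisions per
#' read, and the latent metric targets. Fully deterministic given
#' `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A list of class `cadgaze_study` with elements `cases`,
#'   `readers`, `reads` (tibble with a `recording` list-column), `decisions`,
#'   `latents`, `case_aux` (per-case mask seed and tile table) and `config`.
#' @export
simulate_study <- function(config) {
  assert_that(inherits(config, "generator_config"),
              "`config` must be a generator_config", "cadgaze_config")
  withr::with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(config) {
  des <- config$design
  n_cases <- des$n_tp + des$n_fn + des$n_fnfp + des$n_tn + des$n_fp
  ids <- sprintf("case%03d", seq_len(n_cases))
  cases <- allocate_cases(des, ids, seed = sample.int(.Machine$integer.max, 1))
  cases$image_width <- config$image_width
  cases$image_height <- config$image_height

  # masks, boxes, tile tables, case-level metric factors
  aux <- vector("list", n_cases)
  zmat <- matrix(stats::rnorm(n_cases * 5), n_cases, 5,
                 dimnames = list(NULL, METRIC_NAMES))
  for (i in seq_len(n_cases)) {
    mask_seed <- sample.int(.Machine$integer.max, 1)
    mask <- make_lung_mask(config$image_width, config$image_height,
                           seed = mask_seed,
                           area_range = config$mask_area_range)
    tiles <- grid_tiles(mask, cell = 50)
    grp <- as.character(cases$group[i])
    lesion <- displayed <- NULL
    if (grp %in% c("TP", "FN", "FN_FP")) {
      lesion <- sample_lesion_box(mask, config$lesion_size_range)
      cases[i, c("lesion_x_min", "lesion_y_min", "lesion_x_max",
                 "lesion_y_max")] <- as.list(lesion)
    }
    if (grp == "TP") displayed <- lesion
    if (grp == "FP") displayed <- sample_lesion_box(mask,
                                                    config$lesion_size_range)
    if (grp == "FN_FP") {
      displayed <- sample_lesion_box(mask, config$lesion_size_range,
                                     avoid = lesion, avoid_margin = 50)
    }
    if (!is.null(displayed)) {
      cases[i, c("displayed_x_min", "displayed_y_min", "displayed_x_max",
                 "displayed_y_max")] <- as.list(displayed)
    }
    aux[[i]] <- tibble::tibble(case_id = ids[i], mask_seed = mask_seed,
                               tiles = list(tiles))
  }
  case_aux <- dplyr::bind_rows(aux)
  validate_case_table(cases)

  readers <- config$readers
  pool <- pooled_baselines(readers)
  n_reads <- nrow(readers) * 2L * n_cases
  read_rows <- vector("list", n_reads)
  latent_rows <- vector("list", n_reads)
  dec_rows <- vector("list", n_reads)
  k <- 0L
  for (r in seq_len(nrow(readers))) {
    profile <- readers[r, ]
    for (session in 1:2) {
      for (i in seq_len(n_cases)) {
        has_disp <- !is.na(cases$displayed_x_min[i])
        condition <- if (session == 1L && has_disp) "with_bb" else
          "without_bb"
        res <- simulate_scanpath(
          cases[i, ], condition, profile, config$effects,
          case_aux$tiles[[i]], sampling_rate = config$sampling_rate,
          dispersion = config$dispersion, rho2 = config$rho2,
          case_z = as.list(zmat[i, ]), pool = pool
        )
        k <- k + 1L
        read_rows[[k]] <- tibble::tibble(
          reader = profile$reader_id, session = session,
          case_id = ids[i], condition = condition,
          recording = list(res$recording)
        )
        latent_rows[[k]] <- dplyr::bind_cols(
          tibble::tibble(reader = profile$reader_id, session = session,
                         case_id = ids[i]),
          res$latent
        )
        dec_rows[[k]] <- tibble::tibble(
          reader = profile$reader_id, session = session, case_id = ids[i],
          decision = decide_read(profile, cases$lesion_present[i], has_disp,
                                 session)
        )
      }
    }
  }
  structure(list(cases = cases, readers = readers,
                 reads = dplyr::bind_rows(read_rows),
                 decisions = dplyr::bind_rows(dec_rows),
                 latents = dplyr::bind_rows(latent_rows),
                 case_aux = case_aux, config = config),
            class = "cadgaze_study")
}

#' @export
print.cadgaze_study <- function(x, ...) {
  cat(sprintf("<cadgaze_study> %d cases, %d readers, %d recordings\n",
              nrow(x$cases), nrow(x$readers), nrow(x$reads)))
  invisible(x)
}

#' Draw latent metric tables without synthesising gaze samples
#'
#' Fast path for calibration studies of the inference layer (e.g. type-I
#' error of the condition contrast): draws the latent per-read metric
#' values from the generator's distributional model for `n_cases`
#' lesion-positive (TP-style) cases, skipping scan-path construction. Uses
#' the current RNG state.
#'
#' @param config A [generator_config()].
#' @param n_cases Number of TP cases to draw.
#' @return A long tibble: `reader`, `session`, `case_id`, `condition`,
#'   `metric`, `value` (coverage on the percent scale).
#' @export
simulate_latent_metrics <- function(config, n_cases = 96L) {
  readers <- config$readers
  zmat <- matrix(stats::rnorm(n_cases * 5), n_cases, 5,
                 dimnames = list(NULL, METRIC_NAMES))
  out <- vector("list", nrow(readers) * 2L * n_cases)
  k <- 0L
  for (r in seq_len(nrow(readers))) {
    profile <- readers[r, ]
    for (session in 1:2) {
      for (i in seq_len(n_cases)) {
        lat <- draw_metric_latents(profile, config$effects,
                                   with_bb = session == 1L, on_lesion = TRUE,
                                   case_z = as.list(zmat[i, ]),
                                   dispersion = config$dispersion,
                                   rho2 = config$rho2,
                                   pool = pooled_baselines(readers))
        k <- k + 1L
        out[[k]] <- tibble::tibble(
          reader = profile$reader_id, session = session,
          case_id = sprintf("case%03d", i),
          condition = paste0("session", session),
          metric = c("interpretation_time_s", "dwell_s", "ttff_s",
                     "path_px", "coverage_pct"),
          value = c(lat$time, lat$dwell, lat$ttff, lat$path,
                    100 * lat$coverage)
        )
      }
    }
  }
  dplyr::bind_rows(out)
}
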