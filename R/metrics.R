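# The five gaze metrics, computed from raw 60 Hz gaze samples. No fixation
# detection (I-DT/I-VT) is applied: "first fixation" on the lesion means the
# first valid raw sample inside the lesion AOI, and dwell counts one
# sampling interval per valid in-AOI sample. The gaze polyline connects
# consecutive valid samples, bridging dropout gaps of any length.

#' Construct a gaze recording
#'
#' A gaze recording is one read of one case: an ordered stream of gaze
#' samples with validity flags, the nominal sampling rate, the read
#' duration (start of interpretation to case advance), and the image
#' dimensions.
#'
#' @param samples A data frame with columns `t` (seconds from read start,
#'   strictly increasing), `x`, `y` (pixels, 0-based, origin top-left) and
#'   `valid` (logical).
#' @param sampling_rate Sampling rate in Hz.
#' @param duration Read duration in seconds; must be at least the last
#'   sample time.
#' @param image_width,image_height Image dimensions in pixels.
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(samples, sampling_rate = 60, duration = NULL,
                           image_width, image_height) {
  samples <- tibble::as_tibble(samples)
  needed <- c("t", "x", "y", "valid")
  assert_that(all(needed %in% names(samples)),
              "`samples` needs columns t, x, y, valid", "cadgaze_input")
  if (nrow(samples) > 0) {
    assert_that(all(samples$t >= 0) && !is.unsorted(samples$t, strictly = TRUE),
                "sample times must be non-negative and strictly increasing",
                "cadgaze_input")
  }
  if (is.null(duration)) {
    duration <- if (nrow(samples) > 0) max(samples$t) else 0
  }
  assert_that(is_number(sampling_rate) && sampling_rate > 0,
              "`sampling_rate` must be positive", "cadgaze_input")
  assert_that(nrow(samples) == 0 || duration >= max(samples$t),
              "`duration` must be at least the last sample time",
              "cadgaze_input")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 duration = duration, image_width = image_width,
                 image_height = image_height),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf(
    "<gaze_recording> %d samples (%d valid), %.1f Hz, %.2f s, %d x %d px\n",
    nrow(x$samples), sum(x$samples$valid), x$sampling_rate, x$duration,
    x$image_width, x$image_height))
  invisible(x)
}

#' Lesion area of interest
#'
#' The lesion AOI is the lesion bounding box expanded by `margin` pixels on
#' all four sides and clipped to the image. Membership is inclusive of the
#' expanded boundary. At the study display geometry a 50 px margin subtends
#' roughly 1.1 degrees of visual angle, matching the foveal span.
#'
#' @param box Named numeric (`x_min`, `y_min`, `x_max`, `y_max`), half-open
#'   pixel intervals.
#' @param margin Margin in pixels (non-negative).
#' @param image_width,image_height Optional image dimensions for clipping.
#' @return An object of class `lesion_aoi`.
#' @export
lesion_aoi <- function(box, margin = 50, image_width = Inf,
                       image_height = Inf) {
  assert_that(is_number(margin) && margin >= 0,
              "`margin` must be non-negative", "cadgaze_input")
  out <- list(
    x_min = max(0, box[["x_min"]] - margin),
    y_min = max(0, box[["y_min"]] - margin),
    x_max = min(image_width, box[["x_max"]] + margin),
    y_max = min(image_height, box[["y_max"]] + margin),
    box = box, margin = margin
  )
  structure(out, class = "lesion_aoi")
}

# inclusive membership of points in the expanded AOI
in_aoi <- function(x, y, aoi) {
  x >= aoi$x_min & x <= aoi$x_max & y >= aoi$y_min & y <= aoi$y_max
}

#' Total interpretation time
#'
#' The read duration in seconds, from the start of case interpretation to
#' the case advance. Defined by the read boundaries, not by the gaze
#' samples, so it is unaffected by tracking dropout.
#'
#' @param rec A [gaze_recording()].
#' @return Seconds.
#' @export
interpretation_time <- function(rec) {
  rec$duration
}

#' Dwell time on the lesion AOI
#'
#' Cumulative time the gaze spent inside the lesion area of interest: the
#' number of valid samples inside the AOI times one sampling interval.
#'
#' @param rec A [gaze_recording()].
#' @param aoi A [lesion_aoi()].
#' @return Seconds.
#' @export
dwell_time <- function(rec, aoi) {
  s <- rec$samples
  keep <- s$valid
  sum(in_aoi(s$x[keep], s$y[keep], aoi)) / rec$sampling_rate
}

#' Time to first fixation on the lesion AOI
#'
#' Elapsed time from the start of the read until the gaze first enters the
#' lesion AOI: the timestamp of the earliest valid sample inside the AOI,
#' or `NA` if the gaze never enters it.
#'
#' @inheritParams dwell_time
#' @return Seconds, or `NA_real_` when the AOI is never entered.
#' @export
time_to_first_fixation <- function(rec, aoi) {
  s <- rec$samples
  hit <- s$valid & in_aoi(s$x, s$y, aoi)
  if (!any(hit)) return(NA_real_)
  s$t[which(hit)[1L]]
}

#' Total gaze-path length
#'
#' Sum of Euclidean distances between consecutive valid samples, in pixels.
#' Invalid (dropped) samples are skipped and the path connects across the
#' gap; the longest bridged gap is attached as attribute `max_gap_s` for
#' audit.
#'
#' @param rec A [gaze_recording()].
#' @return Pixels, with attribute `max_gap_s` (seconds; 0 when no gap was
#'   bridged).
#' @export
path_length <- function(rec) {
  s <- rec$samples[rec$samples$valid, ]
  n <- nrow(s)
  if (n < 2) {
    return(structure(0, max_gap_s = 0))
  }
  len <- sum(sqrt(diff(s$x)^2 + diff(s$y)^2))
  gaps <- diff(s$t)
  structure(len, max_gap_s = max(c(0, gaps[gaps > 1.5 / rec$sampling_rate])))
}

#' Lung-field grid coverage
#'
#' Proportion of lung-field grid tiles crossed by the gaze path dilated by
#' a foveal-span buffer. The image is divided into `cell` x `cell` tiles
#' anchored at the origin; a tile belongs to the lung set when its centre
#' pixel lies inside the mask; a lung tile is covered when any of its
#' pixels lies within `buffer` pixels (inclusive) of the polyline through
#' the valid samples. Returns 0 when the recording has no valid samples.
#'
#' @param rec A [gaze_recording()].
#' @param mask Logical lung mask matrix with dimensions matching the
#'   recording's image.
#' @param cell Grid tile side in pixels.
#' @param buffer Dilation of the gaze path in pixels.
#' @return A fraction in \[0, 1\].
#' @export
lung_coverage <- function(rec, mask, cell = 50, buffer = 50) {
  assert_that(nrow(mask) == rec$image_height && ncol(mask) == rec$image_width,
              "mask dimensions must match the recording's image",
              "cadgaze_input")
  tiles <- grid_tiles(mask, cell)
  s <- rec$samples[rec$samples$valid, ]
  if (nrow(s) < 1) {
    assert_that(any(tiles$lung), "mask contains no lung tiles",
                "cadgaze_undefined")
    return(0)
  }
  cov <- coverage_from_tiles(s$x, s$y, tiles, buffer)
  cov$n_covered / cov$n_lung
}

#' Visual angle subtended by a pixel extent
#'
#' Converts an on-screen pixel extent to degrees of visual angle:
#' `2 * atan(extent * pitch / (2 * distance))`.
#'
#' @param extent_px Extent in pixels.
#' @param pixel_pitch_mm Monitor pixel pitch in millimetres.
#' @param viewing_distance_cm Eye-to-screen distance in centimetres.
#' @return Degrees.
#' @examples
#' visual_angle(50, 0.233, 60) # about 1.1 degrees
#' @export
visual_angle <- function(extent_px, pixel_pitch_mm = 0.233,
                         viewing_distance_cm = 60) {
  assert_that(all(extent_px >= 0), "`extent_px` must be non-negative",
              "cadgaze_domain")
  assert_that(is_number(pixel_pitch_mm) && pixel_pitch_mm > 0 &&
                is_number(viewing_distance_cm) && viewing_distance_cm > 0,
              "pitch and distance must be positive", "cadgaze_domain")
  2 * atan(extent_px * pixel_pitch_mm / (2 * viewing_distance_cm * 10)) *
    180 / pi
}

#' Capture ratio of a recording
#'
#' Fraction of expected gaze samples actually recorded as valid during the
#' interpretation period: valid-sample count over
#' `round(duration * sampling_rate)`, capped at 1.
#'
#' @param rec A [gaze_recording()].
#' @return A fraction in \[0, 1\].
#' @export
capture_ratio <- function(rec) {
  assert_that(rec$duration > 0, "capture ratio undefined for zero duration",
              "cadgaze_undefined")
  expected <- round(rec$duration * rec$sampling_rate)
  min(1, sum(rec$samples$valid) / expected)
}

#' Compute the full metric record for one read
#'
#' Computes all five gaze metrics plus the capture ratio for a single
#' recording. Dwell and time to first fixation are `NA` when no lesion box
#' is supplied; coverage is `NA` when no mask (or tile table) is supplied.
#'
#' @param rec A [gaze_recording()].
#' @param lesion_box Optional named box (`x_min`, `y_min`, `x_max`,
#'   `y_max`).
#' @param mask Optional lung mask matrix.
#' @param tiles Optional precomputed [grid_tiles()] table (used instead of
#'   `mask`; the two are equivalent since the tile table is derived from
#'   the mask).
#' @param margin AOI margin in pixels.
#' @param cell,buffer Coverage grid parameters in pixels.
#' @return A one-row tibble: `interpretation_time_s`, `dwell_s`, `ttff_s`,
#'   `path_px`, `coverage`, `capture_ratio`.
#' @export
compute_read_metrics <- function(rec, lesion_box = NULL, mask = NULL,
                                 tiles = NULL, margin = 50, cell = 50,
                                 buffer = 50) {
  dwell <- ttff <- NA_real_
  if (!is.null(lesion_box) && !any(is.na(lesion_box))) {
    aoi <- lesion_aoi(lesion_box, margin, rec$image_width, rec$image_height)
    dwell <- dwell_time(rec, aoi)
    ttff <- time_to_first_fixation(rec, aoi)
  }
  coverage <- NA_real_
  if (is.null(tiles) && !is.null(mask)) tiles <- grid_tiles(mask, cell)
  if (!is.null(tiles)) {
    s <- rec$samples[rec$samples$valid, ]
    if (nrow(s) < 1) {
      coverage <- 0
    } else {
      cov <- coverage_from_tiles(s$x, s$y, tiles, buffer)
      coverage <- cov$n_covered / cov$n_lung
    }
  }
  tibble::tibble(
    interpretation_time_s = interpretation_time(rec),
    dwell_s = dwell,
    ttff_s = ttff,
    path_px = as.numeric(path_length(rec)),
    coverage = coverage,
    capture_ratio = capture_ratio(rec)
  )
}
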