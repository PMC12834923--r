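# Pipeline glue: configuration with the study-standard defaults, the
# metrics stage over a simulated (or loaded) dataset, dataset round-tripping
# on disk, and the end-to-end analysis (validity pairing -> performance
# tables -> mixed models) with run metadata.

#' Pipeline configuration
#'
#' Analysis parameters with the study-standard defaults: 50 px AOI margin,
#' 50 px coverage grid cell, 50 px path buffer, strict 0.5 capture-ratio
#' validity threshold, 60 Hz sampling, and the display geometry (0.233 mm
#' pixel pitch, 60 cm viewing distance, 2560 x 1440 raster).
#'
#' @param margin,cell,buffer Pixel parameters of the AOI and coverage grid.
#' @param validity_threshold Capture-ratio threshold (strict).
#' @param sampling_rate Hz.
#' @param pixel_pitch_mm,viewing_distance_cm Display geometry.
#' @param image_width,image_height Display raster in pixels.
#' @param seed Integer seed for seeded pipeline stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(margin = 50, cell = 50, buffer = 50,
                            validity_threshold = 0.5, sampling_rate = 60,
                            pixel_pitch_mm = 0.233,
                            viewing_distance_cm = 60, image_width = 2560,
                            image_height = 1440, seed = 1L) {
  structure(list(margin = margin, cell = cell, buffer = buffer,
                 validity_threshold = validity_threshold,
                 sampling_rate = sampling_rate,
                 pixel_pitch_mm = pixel_pitch_mm,
                 viewing_distance_cm = viewing_distance_cm,
                 image_width = image_width, image_height = image_height,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_pipeline_config()` returns a [pipeline_config()];
#'   `write_pipeline_config()` returns `path` invisibly. Reading errors
#'   name any missing key.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  needed <- names(formals(pipeline_config))
  missing <- setdiff(needed, names(vals))
  assert_that(length(missing) == 0,
              paste0("config is missing key(s): ",
                     paste(missing, collapse = ", ")),
              "cadgaze_config")
  do.call(pipeline_config, vals[needed])
}

#' Compute the metrics table for a simulated study
#'
#' Runs the five gaze metrics plus the capture ratio over every recording
#' of a [simulate_study()] bundle. The per-case tile table stored in the
#' bundle (derived deterministically from the case's lung mask) supplies
#' the lung grid for coverage.
#'
#' @param bundle A `cadgaze_study`.
#' @param params A [pipeline_config()].
#' @return A tibble with one row per read: `reader`, `session`, `case_id`,
#'   `group`, `condition`, the metric columns of
#'   [compute_read_metrics()].
#' @export
compute_study_metrics <- function(bundle, params = pipeline_config()) {
  assert_that(inherits(bundle, "cadgaze_study"),
              "`bundle` must come from simulate_study()", "cadgaze_input")
  cases <- bundle$cases
  tile_map <- stats::setNames(bundle$case_aux$tiles, bundle$case_aux$case_id)
  reads <- bundle$reads
  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    ci <- match(reads$case_id[i], cases$case_id)
    lesion_box <- NULL
    if (cases$lesion_present[ci]) {
      lesion_box <- c(x_min = cases$lesion_x_min[ci],
                      y_min = cases$lesion_y_min[ci],
                      x_max = cases$lesion_x_max[ci],
                      y_max = cases$lesion_y_max[ci])
    }
    m <- compute_read_metrics(reads$recording[[i]], lesion_box = lesion_box,
                              tiles = tile_map[[reads$case_id[i]]],
                              margin = params$margin, cell = params$cell,
                              buffer = params$buffer)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(reader = reads$reader[i], session = reads$session[i],
                     case_id = reads$case_id[i],
                     group = as.character(cases$group[ci]),
                     condition = reads$condition[i]),
      m
    )
  }
  dplyr::bind_rows(rows)
}

#' Write a simulated study dataset to disk
#'
#' Emits the dataset in open formats: the case table CSV, per-read gaze
#' logs (`gaze/<reader>_s<session>_<case>.csv` with columns `t_sec`,
#' `x_px`, `y_px`, `valid`), the decisions (reads) CSV, the latent truth
#' CSV, lung masks as single-channel PNGs (optional; they are
#' reconstructible from the recorded mask seeds), and a manifest CSV
#' listing every gaze log. Idempotent for a fixed bundle.
#'
#' @param bundle A `cadgaze_study`.
#' @param dir Output directory (created if needed).
#' @param masks Write mask PNGs (`FALSE` by default; full-size masks are
#'   large).
#' @return `dir`, invisibly.
#' @export
write_study_dataset <- function(bundle, dir, masks = FALSE) {
  gaze_dir <- file.path(dir, "gaze")
  dir.create(gaze_dir, recursive = TRUE, showWarnings = FALSE)
  write_case_table(bundle$cases, file.path(dir, "cases.csv"))
  readr::write_csv(bundle$decisions, file.path(dir, "reads.csv"))
  readr::write_csv(bundle$latents, file.path(dir, "latents.csv"))
  readr::write_csv(bundle$case_aux[, c("case_id", "mask_seed")],
                   file.path(dir, "mask_seeds.csv"))
  reads <- bundle$reads
  manifest <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    rec <- reads$recording[[i]]
    file <- sprintf("%s_s%d_%s.csv", reads$reader[i], reads$session[i],
                    reads$case_id[i])
    out <- tibble::tibble(t_sec = rec$samples$t, x_px = rec$samples$x,
                          y_px = rec$samples$y,
                          valid = as.integer(rec$samples$valid))
    readr::write_csv(out, file.path(gaze_dir, file))
    manifest[[i]] <- tibble::tibble(
      reader = reads$reader[i], session = reads$session[i],
      case_id = reads$case_id[i], condition = reads$condition[i],
      file = file.path("gaze", file), duration_s = rec$duration,
      sampling_rate_hz = rec$sampling_rate, n_samples = nrow(rec$samples)
    )
  }
  readr::write_csv(dplyr::bind_rows(manifest),
                   file.path(dir, "manifest.csv"))
  if (masks) {
    mask_dir <- file.path(dir, "masks")
    dir.create(mask_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(bundle$case_aux))) {
      mask <- make_lung_mask(bundle$config$image_width,
                             bundle$config$image_height,
                             seed = bundle$case_aux$mask_seed[i],
                             area_range = bundle$config$mask_area_range)
      png::writePNG(mask * 1,
                    file.path(mask_dir,
                              paste0(bundle$case_aux$case_id[i], ".png")))
    }
  }
  invisible(dir)
}

#' Read one gaze log CSV as a recording
#'
#' @param path Gaze log CSV (`t_sec`, `x_px`, `y_px`, `valid`).
#' @param sampling_rate Hz.
#' @param duration Read duration in seconds; defaults to the manifest value
#'   or, failing that, the last sample time plus one sampling interval.
#' @param image_width,image_height Image dimensions in pixels.
#' @return A [gaze_recording()]. Non-monotone timestamps are rejected.
#' @export
read_gaze_log <- function(path, sampling_rate = 60, duration = NULL,
                          image_width = 2560, image_height = 1440) {
  raw <- readr::read_csv(path, col_types = "dddi")
  samples <- tibble::tibble(t = raw$t_sec, x = raw$x_px, y = raw$y_px,
                            valid = raw$valid == 1)
  if (is.null(duration) && nrow(samples) > 0) {
    duration <- max(samples$t) + 1 / sampling_rate
  }
  gaze_recording(samples, sampling_rate = sampling_rate,
                 duration = duration, image_width = image_width,
                 image_height = image_height)
}

#' Run the full analysis stage
#'
#' From a metrics table, a decisions table and the case table: applies the
#' capture-ratio validity criterion and listwise pairing (TP scope),
#' tabulates diagnostic performance over all reads, fits the per-metric
#' condition mixed models on the paired set, and collects run metadata
#' (parameter values, per-metric sizes, dropped-row counts).
#'
#' @param metrics Metrics table from [compute_study_metrics()].
#' @param reads Decisions table (`reader`, `session`, `case_id`,
#'   `decision`).
#' @param cases Case table.
#' @param params A [pipeline_config()].
#' @return A list of class `cadgaze_analysis`: `pairing` (summary tibble),
#'   `pairs`, `performance`, `fits` (tibble from [fit_all_metrics()]),
#'   `diagnostics` (residual diagnostics per metric), and `metadata`.
#' @export
analyze_study <- function(metrics, reads, cases,
                          params = pipeline_config()) {
  assert_that(nrow(metrics) > 0, "`metrics` is empty", "cadgaze_input")
  assert_that(nrow(reads) > 0, "`reads` is empty", "cadgaze_input")
  pairs <- listwise_pair(metrics, cases, groups = "TP",
                         threshold = params$validity_threshold)
  pairing <- pairing_summary(metrics, cases, groups = "TP",
                             threshold = params$validity_threshold)
  tab <- build_analysis_table(metrics, pairs)
  fits <- fit_all_metrics(tab)
  diag <- dplyr::bind_rows(lapply(fits$fit, residual_diagnostics))
  perf <- performance_table(reads, cases)
  metadata <- list(
    params = unclass(params),
    n_reads_total = nrow(metrics),
    n_pairs = nrow(pairs),
    n_rows_per_metric = table(tab$metric),
    n_dropped_per_metric = attr(tab, "n_dropped"),
    adoption_definition = "session-1 decision concordant with display",
    inference = "Wald (normal), REML",
    package_version = as.character(utils::packageVersion("cadgaze"))
  )
  structure(list(pairing = pairing, pairs = pairs, performance = perf,
                 fits = fits, diagnostics = diag, metadata = metadata),
            class = "cadgaze_analysis")
}

#' @export
print.cadgaze_analysis <- function(x, ...) {
  cat("<cadgaze_analysis>\n")
  cat(sprintf("  %d paired reads over %d readers\n",
              x$metadata$n_pairs, nrow(x$pairing)))
  td <- x$fits[, c("metric", "estimate", "conf.low", "conf.high",
                   "p.value")]
  print(as.data.frame(td), row.names = FALSE)
  invisible(x)
}

#' Run simulation, metrics and analysis end to end
#'
#' Convenience wrapper: [simulate_study()] then [compute_study_metrics()]
#' then [analyze_study()]. Deterministic given the generator seed.
#'
#' @param gen_config A [generator_config()].
#' @param params A [pipeline_config()].
#' @return A list: `bundle`, `metrics`, `analysis`.
#' @export
run_study_pipeline <- function(gen_config = default_generator_config(),
                               params = pipeline_config()) {
  bundle <- simulate_study(gen_config)
  metrics <- compute_study_metrics(bundle, params)
  analysis <- analyze_study(metrics, bundle$decisions, bundle$cases, params)
  list(bundle = bundle, metrics = metrics, analysis = analysis)
}
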