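test_that("zero dropout yields a complete stream with capture ratio 1", {
  mask <- make_lung_mask(640, 360, seed = 2)
  tiles <- grid_tiles(mask, 50)
  box <- withr::with_seed(1, sample_lesion_box(mask, c(30, 60)))
  case <- tibble::tibble(
    case_id = "c1", lesion_present = TRUE, group = "TP",
    lesion_x_min = box[["x_min"]], lesion_y_min = box[["y_min"]],
    lesion_x_max = box[["x_max"]], lesion_y_max = box[["y_max"]],
    displayed_x_min = box[["x_min"]], displayed_y_min = box[["y_min"]],
    displayed_x_max = box[["x_max"]], displayed_y_max = box[["y_max"]],
    image_width = 640, image_height = 360
  )
  prof <- reader_profile("A", 5, 0.8, 1.0, 2500, 0.5, dropout_rate = 0)
  withr::local_seed(5)
  res <- simulate_scanpath(case, "without_bb", prof, condition_effects(),
                           tiles)
  rec <- res$recording
  expect_equal(nrow(rec$samples), round(rec$duration * 60))
  expect_true(all(rec$samples$valid))
  expect_equal(capture_ratio(rec), 1.0)
  # all coordinates inside the image
  expect_true(all(rec$samples$x >= 0 & rec$samples$x <= 639))
  expect_true(all(rec$samples$y >= 0 & rec$samples$y <= 359))
})

test_that("recordings recover their latent targets at zero dropout", {
  mask <- make_lung_mask(640, 360, seed = 3)
  tiles <- grid_tiles(mask, 50)
  box <- withr::with_seed(2, sample_lesion_box(mask, c(30, 60)))
  case <- tibble::tibble(
    case_id = "c1", lesion_present = TRUE, group = "TP",
    lesion_x_min = box[["x_min"]], lesion_y_min = box[["y_min"]],
    lesion_x_max = box[["x_max"]], lesion_y_max = box[["y_max"]],
    displayed_x_min = box[["x_min"]], displayed_y_min = box[["y_min"]],
    displayed_x_max = box[["x_max"]], displayed_y_max = box[["y_max"]],
    image_width = 640, image_height = 360
  )
  prof <- reader_profile("A", 6, 0.8, 1.2, 3000, 0.45, dropout_rate = 0)
  withr::local_seed(77)
  aoi <- lesion_aoi(box, 50, 640, 360)
  n_checked <- 0
  for (i in 1:30) {
    res <- simulate_scanpath(case, "with_bb", prof, condition_effects(),
                             tiles)
    rec <- res$recording
    lat <- res$latent
    expect_equal(interpretation_time(rec), lat$latent_time_s)
    if (lat$clamped) next
    n_checked <- n_checked + 1
    expect_lt(abs(dwell_time(rec, aoi) - lat$latent_dwell_s), 2 / 60)
    expect_lt(abs(time_to_first_fixation(rec, aoi) - lat$latent_ttff_s),
              2 / 60)
    p <- as.numeric(path_length(rec))
    expect_lt(abs(p - lat$latent_path_px),
              0.2 * lat$latent_path_px + 300)
    # realization grain: one stamp can add up to ~9 tiles on coarse grids
    n_lung <- sum(tiles$lung)
    cov <- lung_coverage(rec, mask)
    expect_gt(cov, lat$latent_coverage - 0.02 - 1 / n_lung)
    expect_lt(cov, lat$latent_coverage + 0.06 + 9 / n_lung)
  }
  expect_gte(n_checked, 10)
})

test_that("capture ratio matches the dropout rate in expectation", {
  mask <- make_lung_mask(320, 180, seed = 4)
  tiles <- grid_tiles(mask, 50)
  case <- tibble::tibble(case_id = "c1", lesion_present = FALSE,
                         group = "TN", lesion_x_min = NA_real_,
                         image_width = 320, image_height = 180)
  d <- 0.3
  prof <- reader_profile("A", 4, 0.5, 1, 1500, 0.5, dropout_rate = d)
  withr::local_seed(12)
  ratios <- replicate(120, {
    capture_ratio(simulate_scanpath(case, "without_bb", prof,
                                    condition_effects(), tiles)$recording)
  })
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - (1 - d)), 3 * se + 1e-6)
})

test_that("a full small study has the right shape and is seed-stable", {
  cfg <- small_config(seed = 42)
  bundle <- simulate_study(cfg)
  n_cases <- nrow(bundle$cases)
  expect_equal(n_cases, 9)
  expect_equal(nrow(bundle$reads), 2 * 2 * n_cases)
  expect_equal(nrow(bundle$decisions), nrow(bundle$reads))
  expect_equal(nrow(bundle$latents), nrow(bundle$reads))

  # session 1 shows the prompt exactly on displayed-box cases
  disp_ids <- bundle$cases$case_id[!is.na(bundle$cases$displayed_x_min)]
  s1 <- bundle$reads[bundle$reads$session == 1, ]
  expect_setequal(s1$case_id[s1$condition == "with_bb"],
                  intersect(s1$case_id, disp_ids))
  expect_true(all(bundle$reads$condition[bundle$reads$session == 2] ==
                    "without_bb"))

  again <- simulate_study(small_config(seed = 42))
  expect_identical(bundle$latents, again$latents)
  expect_identical(bundle$reads$recording[[5]]$samples,
                   again$reads$recording[[5]]$samples)
  other <- simulate_study(small_config(seed = 43))
  expect_false(identical(bundle$latents, other$latents))
})

test_that("condition effects shift measured first-entry times as targeted", {
  # many replicate TP cases: measured ttff difference tracks the latent shift
  cfg <- small_config(seed = 9)
  prof <- reader_profile("A", 6, 0.8, 2.0, 2500, 0.5, dropout_rate = 0)
  eff <- condition_effects(d_ttff_s = -1.0, d_time_s = 0, d_dwell_s = 0,
                           d_path_px = 0, d_coverage = 0)
  mask <- make_lung_mask(640, 360, seed = 8)
  tiles <- grid_tiles(mask, 50)
  box <- withr::with_seed(3, sample_lesion_box(mask, c(30, 60)))
  case <- tibble::tibble(
    case_id = "c1", lesion_present = TRUE, group = "TP",
    lesion_x_min = box[["x_min"]], lesion_y_min = box[["y_min"]],
    lesion_x_max = box[["x_max"]], lesion_y_max = box[["y_max"]],
    displayed_x_min = box[["x_min"]], displayed_y_min = box[["y_min"]],
    displayed_x_max = box[["x_max"]], displayed_y_max = box[["y_max"]],
    image_width = 640, image_height = 360
  )
  aoi <- lesion_aoi(box, 50, 640, 360)
  withr::local_seed(21)
  tt <- function(cond) {
    replicate(200, time_to_first_fixation(
      simulate_scanpath(case, cond, prof, eff, tiles)$recording, aoi))
  }
  with_bb <- tt("with_bb")
  without <- tt("without_bb")
  diff_mean <- mean(with_bb) - mean(without)
  mc_se <- sqrt(var(with_bb) / 200 + var(without) / 200)
  # expected mean shift for a median-anchored log-normal multiplier
  expected <- -1.0 * exp((0.4^2) * (1 - 0.5) / 2)
  expect_lt(abs(diff_mean - expected), 4 * mc_se)
})

test_that("latent-only simulation is null-calibrated under zero effects", {
  cfg <- small_config(seed = 1)
  cfg$effects <- condition_effects(0, 0, 0, 0, 0)
  withr::local_seed(14)
  ps <- replicate(30, {
    tab <- simulate_latent_metrics(cfg, n_cases = 12)
    d <- tab[tab$metric == "interpretation_time_s", ]
    s1 <- d$value[d$session == 1]
    s2 <- d$value[d$session == 2]
    t.test(s1, s2, paired = TRUE)$p.value
  })
  # under the null, p-values should not pile up near zero
  expect_gt(min(ps), 1e-4)
  expect_gt(mean(ps > 0.1), 0.5)
})
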