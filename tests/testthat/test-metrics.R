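test_that("interpretation time is the read duration, independent of samples", {
  rec <- make_rec(c(10, 20), c(10, 20), duration = 14.6)
  expect_equal(interpretation_time(rec), 14.6)

  empty <- gaze_recording(tibble::tibble(t = numeric(), x = numeric(),
                                         y = numeric(), valid = logical()),
                          60, duration = 0, image_width = 100,
                          image_height = 100)
  expect_equal(interpretation_time(empty), 0)

  no_valid <- make_rec(c(10, 20), c(10, 20), valid = FALSE, duration = 14.6)
  expect_equal(interpretation_time(no_valid), 14.6)
})

test_that("dwell counts one sampling interval per valid in-AOI sample", {
  box <- c(x_min = 100, y_min = 100, x_max = 140, y_max = 140)
  aoi <- lesion_aoi(box, margin = 50, image_width = 300, image_height = 300)
  rec <- make_rec(rep(120, 90), rep(120, 90))
  expect_equal(dwell_time(rec, aoi), 1.5)  # 90 samples at 60 Hz

  outside <- make_rec(rep(10, 30), rep(10, 30))
  expect_equal(dwell_time(outside, aoi), 0)

  # invalid samples never count
  half <- make_rec(rep(120, 60), rep(120, 60), valid = rep(c(TRUE, FALSE), 30))
  expect_equal(dwell_time(half, aoi), 0.5)
})

test_that("time to first fixation is the first valid in-AOI timestamp", {
  box <- c(x_min = 100, y_min = 100, x_max = 140, y_max = 140)
  aoi <- lesion_aoi(box, 50, 300, 300)
  x <- c(rep(10, 60), rep(120, 30))
  rec <- make_rec(x, x)
  expect_equal(time_to_first_fixation(rec, aoi), 1.0)

  inside_first <- make_rec(c(120, 10), c(120, 10))
  expect_equal(time_to_first_fixation(inside_first, aoi), 0)

  never <- make_rec(rep(10, 50), rep(10, 50))
  expect_true(is.na(time_to_first_fixation(never, aoi)))

  # invalid entry samples are skipped until the first valid one
  late <- make_rec(x, x, valid = c(rep(TRUE, 60), FALSE, rep(TRUE, 29)))
  expect_equal(time_to_first_fixation(late, aoi), 61 / 60)
})

test_that("path length sums distances between consecutive valid samples", {
  rec <- make_rec(c(0, 3), c(0, 4))
  expect_equal(as.numeric(path_length(rec)), 5)

  single <- make_rec(5, 5)
  expect_equal(as.numeric(path_length(single)), 0)

  # invalid samples are bridged and the gap is logged
  gap <- make_rec(c(0, 50, 3), c(0, 50, 4), valid = c(TRUE, FALSE, TRUE))
  expect_equal(as.numeric(path_length(gap)), 5)
  expect_gt(attr(path_length(gap), "max_gap_s"), 0)
})

test_that("visual angle matches the display geometry", {
  expect_equal(round(visual_angle(50, 0.233, 60), 1), 1.1)
  expect_equal(visual_angle(0, 0.233, 60), 0)
  # small-angle regime: doubling distance halves the angle to first order
  a1 <- visual_angle(50, 0.233, 60)
  a2 <- visual_angle(50, 0.233, 120)
  expect_lt(abs(a1 / 2 - a2) / a2, 0.01)
  expect_error(visual_angle(50, 0, 60), class = "cadgaze_domain")
  expect_error(visual_angle(50, 0.233, -1), class = "cadgaze_domain")
})

test_that("coverage handles the trivial extremes", {
  mask <- matrix(TRUE, 100, 100)
  # a path whose buffered band spans the whole image
  rec <- make_rec(c(0, 99), c(50, 50), width = 100, height = 100)
  expect_equal(lung_coverage(rec, mask, cell = 50, buffer = 80), 1.0)

  no_valid <- make_rec(c(10, 20), c(10, 20), valid = FALSE, width = 100,
                       height = 100)
  expect_equal(lung_coverage(no_valid, mask, cell = 50, buffer = 50), 0)

  wrong_dims <- make_rec(10, 10, width = 90, height = 100)
  expect_error(lung_coverage(wrong_dims, mask), class = "cadgaze_input")
  empty_mask <- matrix(FALSE, 100, 100)
  expect_error(lung_coverage(rec, empty_mask), class = "cadgaze_undefined")
})

test_that("capture ratio uses the expected-sample denominator", {
  rec <- make_rec(rep(1, 900), rep(1, 900), duration = 30)
  expect_equal(capture_ratio(rec), 0.5)  # 900 / 1800

  full <- make_rec(rep(1, 60), rep(1, 60), duration = 1)
  expect_equal(capture_ratio(full), 1)

  zero_dur <- gaze_recording(tibble::tibble(t = numeric(), x = numeric(),
                                            y = numeric(),
                                            valid = logical()),
                             60, duration = 0, image_width = 10,
                             image_height = 10)
  expect_error(capture_ratio(zero_dur), class = "cadgaze_undefined")
})

test_that("metric invariants hold over randomized recordings", {
  withr::local_seed(2024)
  for (i in 1:40) {
    w <- sample(150:350, 1); h <- sample(150:350, 1)
    n <- sample(2:200, 1)
    rec <- make_rec(runif(n, 0, w - 1), runif(n, 0, h - 1),
                    valid = runif(n) < 0.85,
                    duration = n / 60 + runif(1, 0, 0.5),
                    width = w, height = h)
    box <- c(x_min = runif(1, 0, w - 40), y_min = runif(1, 0, h - 40))
    box <- c(box, x_max = box[["x_min"]] + runif(1, 10, 40),
             y_max = box[["y_min"]] + runif(1, 10, 40))
    mask <- random_blob_mask(w, h)

    it <- interpretation_time(rec)
    aoi0 <- lesion_aoi(box, 0, w, h)
    aoi50 <- lesion_aoi(box, 50, w, h)
    aoi90 <- lesion_aoi(box, 90, w, h)
    d0 <- dwell_time(rec, aoi0); d50 <- dwell_time(rec, aoi50)
    d90 <- dwell_time(rec, aoi90)
    expect_lte(d90, it + 1e-12)
    expect_true(d0 <= d50 && d50 <= d90)  # monotone in margin
    tf <- time_to_first_fixation(rec, aoi50)
    if (!is.na(tf)) {
      expect_lte(tf, it)
      # invariant to what happens after first entry
      cut <- rec
      first <- which(cut$samples$valid &
                       cadgaze:::in_aoi(cut$samples$x, cut$samples$y, aoi50))[1]
      cut$samples <- cut$samples[seq_len(first), ]
      expect_equal(time_to_first_fixation(cut, aoi50), tf)
    }
    cov30 <- lung_coverage(rec, mask, cell = 50, buffer = 30)
    cov60 <- lung_coverage(rec, mask, cell = 50, buffer = 60)
    expect_gte(cov30, 0); expect_lte(cov60, 1)
    expect_lte(cov30, cov60)  # monotone in buffer

    p <- as.numeric(path_length(rec))
    shifted <- rec
    shifted$samples$x <- shifted$samples$x + 13.7
    shifted$samples$y <- shifted$samples$y - 4.2
    expect_equal(as.numeric(path_length(shifted)), p, tolerance = 1e-9)
    scaled <- rec
    scaled$samples$x <- scaled$samples$x * 2.5
    scaled$samples$y <- scaled$samples$y * 2.5
    expect_equal(as.numeric(path_length(scaled)), 2.5 * p, tolerance = 1e-9)
  }
})

test_that("overlay renderer matches input dimensions and is deterministic", {
  mask <- make_lung_mask(128, 96, seed = 6)
  withr::local_seed(3)
  rec <- make_rec(runif(12, 0, 127), runif(12, 0, 95), width = 128,
                  height = 96)
  img <- render_overlay(rec, mask, buffer = 20)
  expect_equal(dim(img), c(96, 128, 3))
  expect_true(all(img >= 0 & img <= 1))
  expect_identical(img, render_overlay(rec, mask, buffer = 20))

  empty <- make_rec(numeric(), numeric(), width = 128, height = 96,
                    duration = 1)
  img0 <- render_overlay(empty, mask, buffer = 20)
  expect_equal(dim(img0), c(96, 128, 3))

  p <- plot_gaze_overlay(rec, mask)
  expect_s3_class(p, "ggplot")
})
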