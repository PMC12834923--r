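toy_cases <- function() {
  tibble::tibble(
    case_id = c("p1", "p2", "p3", "n1"),
    lesion_present = c(TRUE, TRUE, TRUE, FALSE),
    group = factor(c("TP", "TP", "FN", "TN"),
                   levels = c("TP", "FN", "FN_FP", "TN", "FP")),
    lesion_x_min = c(1, 1, 1, NA), lesion_y_min = c(1, 1, 1, NA),
    lesion_x_max = c(2, 2, 2, NA), lesion_y_max = c(2, 2, 2, NA),
    displayed_x_min = c(1, 1, NA, NA), displayed_y_min = c(1, 1, NA, NA),
    displayed_x_max = c(2, 2, NA, NA), displayed_y_max = c(2, 2, NA, NA),
    image_width = 100, image_height = 100
  )
}

toy_reads <- function(decisions_s1, decisions_s2) {
  dplyr::bind_rows(
    tibble::tibble(reader = "A", session = 1,
                   case_id = c("p1", "p2", "p3", "n1"),
                   decision = decisions_s1),
    tibble::tibble(reader = "A", session = 2,
                   case_id = c("p1", "p2", "p3", "n1"),
                   decision = decisions_s2)
  )
}

test_that("accuracy counts correct decisions per cell", {
  reads <- toy_reads(c("positive", "positive", "positive", "negative"),
                     c("positive", "positive", "positive", "negative"))
  acc <- accuracy_by_group(reads, toy_cases())
  expect_true(all(acc$accuracy_pct == 100))

  # 3 of 4 correct in session 1
  reads2 <- toy_reads(c("positive", "negative", "positive", "negative"),
                      c("positive", "positive", "positive", "negative"))
  acc2 <- accuracy_by_group(reads2, toy_cases())
  s1 <- acc2[acc2$session == 1, ]
  expect_equal(sum(s1$n * s1$accuracy_pct / 100), 3)
  expect_equal(s1$accuracy_pct[s1$group == "TP"], 50)
})

test_that("improved/worsened counts track decision flips", {
  same <- toy_reads(c("positive", "negative", "positive", "negative"),
                    c("positive", "negative", "positive", "negative"))
  iw <- improved_worsened(same, toy_cases(), "TP")
  expect_equal(c(iw$improved, iw$worsened), c(0L, 0L))

  # one flip each way within TP
  flip <- toy_reads(c("positive", "negative", "positive", "negative"),
                    c("negative", "positive", "positive", "negative"))
  iw2 <- improved_worsened(flip, toy_cases(), "TP")
  expect_equal(c(iw2$improved, iw2$worsened), c(1L, 1L))

  # algebraic identity: improved - worsened = correct_s1 - correct_s2
  withr::local_seed(4)
  for (i in 1:10) {
    d1 <- sample(c("positive", "negative"), 4, replace = TRUE)
    d2 <- sample(c("positive", "negative"), 4, replace = TRUE)
    reads <- toy_reads(d1, d2)
    iw <- improved_worsened(reads, toy_cases(), "TP")
    acc <- accuracy_by_group(reads, toy_cases())
    tp <- acc[acc$group == "TP", ]
    c1 <- tp$n[tp$session == 1] * tp$accuracy_pct[tp$session == 1] / 100
    c2 <- tp$n[tp$session == 2] * tp$accuracy_pct[tp$session == 2] / 100
    expect_equal(iw$improved - iw$worsened, c1 - c2)
  }
})

test_that("unpaired cases are excluded from flip counts with a warning", {
  reads <- toy_reads(c("positive", "negative", "positive", "negative"),
                     c("negative", "positive", "positive", "negative"))
  reads <- reads[-6, ]  # drop p2 in session 2
  expect_warning(iw <- improved_worsened(reads, toy_cases(), "TP"),
                 "unpaired")
  # only p1 remains paired: correct in session 1, incorrect in session 2
  expect_equal(c(iw$improved, iw$worsened), c(1L, 0L))
})

test_that("adoption is session-1 concordance with the display", {
  # always agree with the display: positive where a box is, negative where not
  agree <- toy_reads(c("positive", "positive", "negative", "negative"),
                     c("negative", "negative", "negative", "negative"))
  expect_equal(bb_adoption_rate(agree, toy_cases())$adoption_pct, 100)
  # TP group: 1 of 2 concordant
  half <- toy_reads(c("positive", "negative", "negative", "negative"),
                    c("negative", "negative", "negative", "negative"))
  expect_equal(bb_adoption_rate(half, toy_cases(), "TP")$adoption_pct, 50)
  # for the box-free TN group, adoption coincides with in-group specificity
  tn <- bb_adoption_rate(half, toy_cases(), "TN")
  expect_equal(tn$adoption_pct, 100)
  expect_error(bb_adoption_rate(half, toy_cases(), "FP"),
               class = "cadgaze_undefined")
})

test_that("sensitivity/specificity use lesion truth, not group labels", {
  perfect <- toy_reads(c("positive", "positive", "positive", "negative"),
                       c("positive", "positive", "positive", "negative"))
  op <- reader_sensitivity_specificity(perfect, toy_cases(), 1)
  expect_equal(c(op$sensitivity_pct, op$specificity_pct), c(100, 100))

  # one miss (p3) and one false alarm (n1) in a 3+/1- set
  mixed <- toy_reads(c("positive", "positive", "negative", "positive"),
                     rep("negative", 4))
  op2 <- reader_sensitivity_specificity(mixed, toy_cases(), 1)
  expect_equal(op2$sensitivity_pct, 100 * 2 / 3)
  expect_equal(op2$specificity_pct, 0)

  # relabelling display groups must not change the operating point
  relabeled <- toy_cases()
  relabeled$group <- factor(c("FN", "FN_FP", "TP", "FP"),
                            levels = levels(relabeled$group))
  op3 <- reader_sensitivity_specificity(mixed, relabeled, 1)
  expect_equal(op3$sensitivity_pct, op2$sensitivity_pct)
  expect_equal(op3$specificity_pct, op2$specificity_pct)
})

test_that("full adoption parameter forces prompt-following behaviour", {
  readers <- dplyr::bind_rows(
    reader_profile("A", 3, 0.5, 0.8, 1500, 0.5, dropout_rate = 0,
                   adoption = 1.0),
    reader_profile("B", 4, 0.7, 1.0, 2000, 0.6, dropout_rate = 0,
                   adoption = 1.0)
  )
  bundle <- simulate_study(small_config(seed = 13, n_tp = 6, n_fp = 3,
                                        readers = readers))
  acc <- accuracy_by_group(bundle$decisions, bundle$cases)
  s1 <- acc[acc$session == 1, ]
  expect_true(all(s1$accuracy_pct[s1$group == "TP"] == 100))
  expect_true(all(s1$accuracy_pct[s1$group == "FP"] == 0))
  tot <- bb_adoption_rate(bundle$decisions, bundle$cases)
  expect_true(all(tot$adoption_pct == 100))
})

test_that("percentages are bounded with logged denominators", {
  bundle <- simulate_study(small_config(seed = 31))
  perf <- performance_table(bundle$decisions, bundle$cases)
  expect_true(all(perf$accuracy$accuracy_pct >= 0 &
                    perf$accuracy$accuracy_pct <= 100))
  expect_true(all(perf$adoption$adoption_pct >= 0 &
                    perf$adoption$adoption_pct <= 100))
  expect_true(all(c("n") %in% names(perf$accuracy)))
  expect_true(all(c("n_pos", "n_neg") %in% names(perf$operating_point)))
})
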