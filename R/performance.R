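# Diagnostic-performance and prompt-adoption tabulation. All reads are used
# regardless of eye-tracking validity. Decisions are binary
# (positive = lesion called present); a read is correct when the decision
# matches lesion presence. "BB adoption" is operationalised as concordance
# of the session-1 decision with the display (positive when a box was
# shown, negative when not) -- the only definition consistent with
# reporting an adoption rate for the box-free TN group.

join_reads_cases <- function(reads, cases) {
  reads <- tibble::as_tibble(reads)
  out <- dplyr::left_join(
    reads,
    cases[, c("case_id", "lesion_present", "group", "displayed_x_min")],
    by = "case_id"
  )
  assert_that(!any(is.na(out$group)),
              "every read's case needs a group label", "cadgaze_input")
  out$correct <- (out$decision == "positive") == out$lesion_present
  out$box_displayed <- !is.na(out$displayed_x_min)
  out
}

#' Accuracy per reader, group and session
#'
#' Percentage of correct decisions (positive iff a lesion is present) per
#' reader x group x session cell, with the cell denominator.
#'
#' @param reads Decisions table: `reader`, `session`, `case_id`,
#'   `decision` (`"positive"`/`"negative"`).
#' @param cases Case table with `group` and `lesion_present`.
#' @return A tibble: `reader`, `group`, `session`, `n`, `accuracy_pct`.
#' @export
accuracy_by_group <- function(reads, cases) {
  x <- join_reads_cases(reads, cases)
  dplyr::summarise(
    dplyr::group_by(x, .data$reader, .data$group, .data$session),
    n = dplyr::n(), accuracy_pct = 100 * mean(.data$correct),
    .groups = "drop"
  )
}

#' Improved and worsened counts between sessions
#'
#' Counts, within one case group, the cases whose decision changed from
#' incorrect in session 2 (unprompted) to correct in session 1 (prompted)
#' -- improved -- and the reverse -- worsened. Unpaired cases are excluded
#' with a warning.
#'
#' @inheritParams accuracy_by_group
#' @param group A single group label.
#' @return A tibble per reader: `reader`, `improved`, `worsened`.
#' @export
improved_worsened <- function(reads, cases, group = "TP") {
  x <- join_reads_cases(reads, cases)
  x <- dplyr::filter(x, as.character(.data$group) == !!group)
  wide <- tidyr::pivot_wider(
    x[, c("reader", "case_id", "session", "correct")],
    names_from = "session", values_from = "correct", names_prefix = "s"
  )
  if (!"s1" %in% names(wide)) wide$s1 <- NA
  if (!"s2" %in% names(wide)) wide$s2 <- NA
  unpaired <- is.na(wide$s1) | is.na(wide$s2)
  if (any(unpaired)) {
    warning(sum(unpaired), " unpaired case(s) excluded from improved/",
            "worsened counts")
    wide <- wide[!unpaired, ]
  }
  dplyr::summarise(
    dplyr::group_by(wide, .data$reader),
    improved = sum(.data$s1 & !.data$s2),
    worsened = sum(!.data$s1 & .data$s2),
    .groups = "drop"
  )
}

#' Bounding-box adoption rate
#'
#' Proportion of session-1 decisions concordant with the display: positive
#' when a box was displayed, negative when not. Computed per reader, within
#' one group or over all cases.
#'
#' @inheritParams accuracy_by_group
#' @param group A group label, or `NULL` for the total over all cases.
#' @return A tibble: `reader`, `n`, `adoption_pct`.
#' @export
bb_adoption_rate <- function(reads, cases, group = NULL) {
  x <- dplyr::filter(join_reads_cases(reads, cases), .data$session == 1)
  if (!is.null(group)) {
    x <- dplyr::filter(x, as.character(.data$group) == !!group)
  }
  assert_that(nrow(x) > 0, "no session-1 reads in scope: rate undefined",
              "cadgaze_undefined")
  x$concordant <- (x$decision == "positive") == x$box_displayed
  dplyr::summarise(
    dplyr::group_by(x, .data$reader),
    n = dplyr::n(), adoption_pct = 100 * mean(.data$concordant),
    .groups = "drop"
  )
}

#' Reader sensitivity and specificity per session
#'
#' Sensitivity over all lesion-positive cases and specificity over all
#' lesion-negative cases (defined by `lesion_present`, never by the display
#' group), per reader for one session.
#'
#' @inheritParams accuracy_by_group
#' @param session Session number (1 or 2).
#' @return A tibble: `reader`, `n_pos`, `n_neg`, `sensitivity_pct`,
#'   `specificity_pct`.
#' @export
reader_sensitivity_specificity <- function(reads, cases, session = 1) {
  x <- dplyr::filter(join_reads_cases(reads, cases),
                     .data$session == !!session)
  assert_that(any(x$lesion_present) && any(!x$lesion_present),
              "need both lesion-positive and lesion-negative reads",
              "cadgaze_undefined")
  dplyr::summarise(
    dplyr::group_by(x, .data$reader),
    n_pos = sum(.data$lesion_present),
    n_neg = sum(!.data$lesion_present),
    sensitivity_pct =
      100 * mean(.data$decision[.data$lesion_present] == "positive"),
    specificity_pct =
      100 * mean(.data$decision[!.data$lesion_present] == "negative"),
    .groups = "drop"
  )
}

#' Full diagnostic-performance table
#'
#' Assembles the per-reader performance summary: accuracy per group and
#' session, improved/worsened counts per group, adoption rates per group
#' and in total, and session-level sensitivity/specificity. Every
#' percentage is accompanied by its denominator.
#'
#' @inheritParams accuracy_by_group
#' @return A named list of tibbles: `accuracy`, `improved_worsened`,
#'   `adoption`, `operating_point`.
#' @export
performance_table <- function(reads, cases) {
  groups <- unique(as.character(cases$group))
  iw <- dplyr::bind_rows(lapply(groups, function(g) {
    dplyr::mutate(improved_worsened(reads, cases, g), group = g,
                  .before = 1)
  }))
  ad <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(groups, function(g) {
      dplyr::mutate(bb_adoption_rate(reads, cases, g), group = g,
                    .before = 1)
    })),
    dplyr::mutate(bb_adoption_rate(reads, cases, NULL), group = "Total",
                  .before = 1)
  )
  op <- dplyr::bind_rows(lapply(1:2, function(s) {
    dplyr::mutate(reader_sensitivity_specificity(reads, cases, s),
                  session = s, .before = 1)
  }))
  list(accuracy = accuracy_by_group(reads, cases), improved_worsened = iw,
       adoption = ad, operating_point = op)
}
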