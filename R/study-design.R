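# Case allocation for the CAD-display reader study. The display shows a
# bounding box (BB) on some cases; the five display-level groups are
#   TP    lesion present, BB correctly on the lesion
#   FN    lesion present, no BB anywhere
#   FN_FP lesion present, BB elsewhere (not on the lesion)
#   TN    no lesion, no BB
#   FP    no lesion, BB present
# Group counts fix the display operating point (sensitivity/specificity).

CASE_GROUPS <- c("TP", "FN", "FN_FP", "TN", "FP")

#' Study design configuration
#'
#' Counts per display-level case group. The display-level sensitivity implied
#' by the counts is `n_tp / (n_tp + n_fn + n_fnfp)` and the specificity is
#' `n_tn / (n_tn + n_fp)`; when `target_sensitivity` / `target_specificity`
#' are supplied they are checked against the counts.
#'
#' @param n_tp,n_fn,n_fnfp,n_tn,n_fp Non-negative case counts per group.
#' @param target_sensitivity,target_specificity Optional fractions in
#'   \[0, 1\] that the counts must reproduce exactly.
#' @return A list of class `design_config`.
#' @examples
#' design_config(96, 12, 12, 48, 12)
#' @export
design_config <- function(n_tp = 96, n_fn = 12, n_fnfp = 12, n_tn = 48,
                          n_fp = 12, target_sensitivity = NULL,
                          target_specificity = NULL) {
  counts <- c(n_tp = n_tp, n_fn = n_fn, n_fnfp = n_fnfp, n_tn = n_tn,
              n_fp = n_fp)
  for (nm in names(counts)) {
    assert_that(is_count(counts[[nm]]),
                paste0("`", nm, "` must be a non-negative integer"),
                "cadgaze_config")
  }
  n_pos <- n_tp + n_fn + n_fnfp
  n_neg <- n_tn + n_fp
  sens <- if (n_pos > 0) n_tp / n_pos else NA_real_
  spec <- if (n_neg > 0) n_tn / n_neg else NA_real_
  if (!is.null(target_sensitivity)) {
    assert_that(isTRUE(all.equal(sens, target_sensitivity)),
                "group counts do not reproduce `target_sensitivity`",
                "cadgaze_config")
  }
  if (!is.null(target_specificity)) {
    assert_that(isTRUE(all.equal(spec, target_specificity)),
                "group counts do not reproduce `target_specificity`",
                "cadgaze_config")
  }
  structure(list(n_tp = n_tp, n_fn = n_fn, n_fnfp = n_fnfp, n_tn = n_tn,
                 n_fp = n_fp, sensitivity = sens, specificity = spec),
            class = "design_config")
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>\n")
  cat(sprintf("  TP %d  FN %d  FN_FP %d  TN %d  FP %d  (n = %d)\n",
              x$n_tp, x$n_fn, x$n_fnfp, x$n_tn, x$n_fp,
              x$n_tp + x$n_fn + x$n_fnfp + x$n_tn + x$n_fp))
  cat(sprintf("  display sensitivity %.3f, specificity %.3f\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Randomly allocate case identifiers to display groups
#'
#' Assigns each case identifier to one of the five display-level groups by a
#' seeded random permutation, with exactly the configured count per group.
#' Lesion-positive groups (TP, FN, FN_FP) receive `lesion_present = TRUE`.
#' Box coordinates are left `NA`; the synthetic-data generator (or an
#' external annotation table) fills them in.
#'
#' @param config A [design_config()].
#' @param case_ids Character vector of unique case identifiers; its length
#'   must equal the total of the configured counts.
#' @param seed Integer seed; the allocation is deterministic given the seed.
#' @return A tibble with one row per case: `case_id`, `lesion_present`,
#'   `group` (factor with levels TP, FN, FN_FP, TN, FP), box coordinate
#'   columns (`lesion_x_min`, ..., `displayed_y_max`, all `NA`), and
#'   `image_width`/`image_height` (`NA`).
#' @export
allocate_cases <- function(config, case_ids, seed = 1L) {
  assert_that(inherits(config, "design_config"),
              "`config` must be a design_config", "cadgaze_config")
  n_total <- config$n_tp + config$n_fn + config$n_fnfp + config$n_tn +
    config$n_fp
  case_ids <- as.character(case_ids)
  assert_that(length(case_ids) == n_total,
              sprintf("expected %d case ids, got %d", n_total,
                      length(case_ids)),
              "cadgaze_config")
  assert_that(!anyDuplicated(case_ids), "case ids must be unique",
              "cadgaze_config")
  groups <- factor(rep(CASE_GROUPS,
                       times = c(config$n_tp, config$n_fn, config$n_fnfp,
                                 config$n_tn, config$n_fp)),
                   levels = CASE_GROUPS)
  perm <- withr::with_seed(seed, sample.int(n_total))
  groups <- groups[order(perm)]
  tibble::tibble(
    case_id = case_ids,
    lesion_present = groups %in% c("TP", "FN", "FN_FP"),
    group = groups,
    lesion_x_min = NA_real_, lesion_y_min = NA_real_,
    lesion_x_max = NA_real_, lesion_y_max = NA_real_,
    displayed_x_min = NA_real_, displayed_y_min = NA_real_,
    displayed_x_max = NA_real_, displayed_y_max = NA_real_,
    image_width = NA_real_, image_height = NA_real_
  )
}

# groups whose cases carry a displayed box
DISPLAYED_GROUPS <- c("TP", "FN_FP", "FP")

#' Validate a case table
#'
#' Checks the structural invariants of a case table: lesion-positive groups
#' carry a lesion box, negative groups do not; TP/FN_FP/FP carry a displayed
#' box, FN/TN do not; TP displayed boxes equal the lesion box; FN_FP
#' displayed boxes do not intersect the lesion area of interest (lesion box
#' expanded by `margin`).
#'
#' @param cases A case tibble as from [allocate_cases()] (boxes may be
#'   filled in or all `NA` for a bare allocation).
#' @param margin AOI margin in pixels used for the FN_FP disjointness check.
#' @return `cases`, invisibly; errors describe the first violated invariant.
#' @export
validate_case_table <- function(cases, margin = 50) {
  has_lesion <- !is.na(cases$lesion_x_min)
  has_disp <- !is.na(cases$displayed_x_min)
  pos <- cases$group %in% c("TP", "FN", "FN_FP")
  assert_that(all(cases$lesion_present == pos),
              "lesion_present must match the group label", "cadgaze_invalid")
  if (any(has_lesion | has_disp)) {
    assert_that(all(has_lesion[pos]) && !any(has_lesion[!pos]),
                "lesion boxes must be present exactly on TP/FN/FN_FP cases",
                "cadgaze_invalid")
    disp <- cases$group %in% DISPLAYED_GROUPS
    assert_that(all(has_disp == disp),
                "displayed boxes must be present exactly on TP/FN_FP/FP cases",
                "cadgaze_invalid")
    tp <- cases$group == "TP"
    same <- cases$lesion_x_min[tp] == cases$displayed_x_min[tp] &
      cases$lesion_y_min[tp] == cases$displayed_y_min[tp] &
      cases$lesion_x_max[tp] == cases$displayed_x_max[tp] &
      cases$lesion_y_max[tp] == cases$displayed_y_max[tp]
    assert_that(all(same), "TP displayed boxes must equal the lesion box",
                "cadgaze_invalid")
    fnfp <- which(cases$group == "FN_FP")
    for (i in fnfp) {
      sep <- cases$displayed_x_max[i] <= cases$lesion_x_min[i] - margin ||
        cases$displayed_x_min[i] >= cases$lesion_x_max[i] + margin ||
        cases$displayed_y_max[i] <= cases$lesion_y_min[i] - margin ||
        cases$displayed_y_min[i] >= cases$lesion_y_max[i] + margin
      assert_that(sep,
                  "FN_FP displayed boxes must not intersect the lesion AOI",
                  "cadgaze_invalid")
    }
  }
  invisible(cases)
}

#' Display-level sensitivity of a case allocation
#'
#' Fraction of lesion-positive cases whose displayed box correctly marks the
#' lesion (i.e. the TP group).
#'
#' @param cases A case tibble.
#' @return A fraction in \[0, 1\].
#' @export
display_sensitivity <- function(cases) {
  pos <- cases$lesion_present
  assert_that(any(pos), "no lesion-positive cases: sensitivity is undefined",
              "cadgaze_undefined")
  sum(cases$group[pos] == "TP") / sum(pos)
}

#' Display-level specificity of a case allocation
#'
#' Fraction of lesion-negative cases with no displayed box (i.e. the TN
#' group).
#'
#' @inheritParams display_sensitivity
#' @return A fraction in \[0, 1\].
#' @export
display_specificity <- function(cases) {
  neg <- !cases$lesion_present
  assert_that(any(neg), "no lesion-negative cases: specificity is undefined",
              "cadgaze_undefined")
  sum(cases$group[neg] == "TN") / sum(neg)
}

#' Read or write a case table CSV
#'
#' The CSV schema follows bounding-box annotation conventions: one row per
#' case with `case_id`, `lesion_present`, `group`, lesion and displayed box
#' coordinates (`*_x_min`, `*_y_min`, `*_x_max`, `*_y_max`; empty when
#' absent), and image dimensions.
#'
#' @param cases A case tibble.
#' @param path File path.
#' @return `read_case_table()` returns the case tibble;
#'   `write_case_table()` returns `path` invisibly.
#' @export
write_case_table <- function(cases, path) {
  readr::write_csv(cases, path, na = "")
  invisible(path)
}

#' @rdname write_case_table
#' @export
read_case_table <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      case_id = readr::col_character(),
      lesion_present = readr::col_logical(),
      group = readr::col_character(),
      .default = readr::col_double()
    ),
    na = c("", "NA")
  )
  out$group <- factor(out$group, levels = CASE_GROUPS)
  validate_case_table(out)
}
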