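# Capture-ratio validity filtering and listwise pairing across sessions.
# A read is valid when strictly more than `threshold` (default 50%) of the
# expected samples were captured; the paired analysis set per reader is the
# intersection of the valid case sets of the two sessions. Diagnostic
# performance, by contrast, always uses all reads.

#' Flag valid reads by capture ratio
#'
#' @param records A data frame with columns `reader`, `session`, `case_id`
#'   and `capture_ratio` (e.g. a metrics table).
#' @param threshold Validity threshold; a read is valid when its capture
#'   ratio is strictly greater than this.
#' @return The input with a logical `valid` column added.
#' @export
flag_valid <- function(records, threshold = 0.5) {
  assert_that("capture_ratio" %in% names(records),
              "`records` needs a capture_ratio column", "cadgaze_input")
  dplyr::mutate(tibble::as_tibble(records),
                valid = .data$capture_ratio > threshold)
}

#' Keep only valid reads
#'
#' @inheritParams flag_valid
#' @return The subset of `records` with capture ratio strictly above the
#'   threshold.
#' @export
filter_valid <- function(records, threshold = 0.5) {
  dplyr::filter(flag_valid(records, threshold), .data$valid)
}

#' Listwise pairing of valid reads across sessions
#'
#' For each reader, intersects the valid case sets of session 1 and
#' session 2, restricted to `groups` (the primary analysis uses TP cases
#' only). Only cases valid in both sessions enter the paired metric
#' analysis.
#'
#' @param records A data frame with `reader`, `session`, `case_id`,
#'   `capture_ratio` covering both sessions.
#' @param cases Optional case table used to restrict to `groups`; omit it
#'   (with `groups = NULL`) to pair over all cases in `records`.
#' @param groups Character vector of group labels to keep (default `"TP"`).
#' @param threshold Validity threshold (strict).
#' @return A tibble of paired reads: `reader`, `case_id`.
#' @export
listwise_pair <- function(records, cases = NULL, groups = "TP",
                          threshold = 0.5) {
  records <- tibble::as_tibble(records)
  if (!is.null(cases) && !is.null(groups)) {
    keep_ids <- cases$case_id[as.character(cases$group) %in% groups]
    records <- dplyr::filter(records, .data$case_id %in% keep_ids)
  }
  valid <- filter_valid(records, threshold)
  s1 <- dplyr::distinct(dplyr::filter(valid, .data$session == 1),
                        .data$reader, .data$case_id)
  s2 <- dplyr::distinct(dplyr::filter(valid, .data$session == 2),
                        .data$reader, .data$case_id)
  dplyr::arrange(dplyr::inner_join(s1, s2, by = c("reader", "case_id")),
                 .data$reader, .data$case_id)
}

#' Per-reader pairing summary
#'
#' Reports, per reader, the number of valid reads in each session (within
#' scope), the number of listwise pairs, and the pair percentage relative
#' to the scoped case count.
#'
#' @inheritParams listwise_pair
#' @return A tibble: `reader`, `n_valid_s1`, `n_valid_s2`, `n_pairs`,
#'   `pct_pairs`.
#' @export
pairing_summary <- function(records, cases = NULL, groups = "TP",
                            threshold = 0.5) {
  records <- tibble::as_tibble(records)
  if (!is.null(cases) && !is.null(groups)) {
    keep_ids <- cases$case_id[as.character(cases$group) %in% groups]
    records <- dplyr::filter(records, .data$case_id %in% keep_ids)
  }
  n_scope <- dplyr::n_distinct(records$case_id)
  valid <- filter_valid(records, threshold)
  per_session <- tidyr::pivot_wider(
    dplyr::count(valid, .data$reader, .data$session),
    names_from = "session", values_from = "n", names_prefix = "n_valid_s",
    values_fill = 0L
  )
  for (col in c("n_valid_s1", "n_valid_s2")) {
    if (!col %in% names(per_session)) per_session[[col]] <- 0L
  }
  pairs <- listwise_pair(records, threshold = threshold)
  n_pairs <- dplyr::count(pairs, .data$reader, name = "n_pairs")
  out <- dplyr::left_join(
    per_session[, c("reader", "n_valid_s1", "n_valid_s2")], n_pairs,
    by = "reader"
  )
  out$n_pairs[is.na(out$n_pairs)] <- 0L
  out$pct_pairs <- 100 * out$n_pairs / n_scope
  dplyr::arrange(out, .data$reader)
}
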