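# Condition-contrast inference: for each gaze metric, a linear mixed model
#   value ~ condition + (1 | case_id) + (1 | reader)
# with crossed random intercepts (every reader reads every case), fitted by
# REML via lme4. The fixed effect is the session1 - session2 contrast
# (positive = larger under prompt display); inference is Wald (normal
# reference), reported in the fit metadata.

ANALYSIS_METRICS <- c("interpretation_time_s", "dwell_s", "ttff_s",
                      "path_px", "coverage_pct")

#' Build the long analysis table for the paired metric models
#'
#' Restricts the metrics table to the listwise-paired reader x case set,
#' keeps both sessions of each pair, and pivots the five metrics to long
#' format (one model row per read per metric). Coverage is rescaled to
#' percentage points to match the reporting scale. Row counts are
#' reconciled against the pairing: each metric must contribute exactly two
#' rows per pair before per-metric missing values (never-fixated reads) are
#' dropped.
#'
#' @param metrics A metrics table with `reader`, `session`, `case_id` and
#'   the five metric columns (`interpretation_time_s`, `dwell_s`, `ttff_s`,
#'   `path_px`, `coverage`).
#' @param pairs A paired-set tibble from [listwise_pair()].
#' @return A tibble: `metric`, `reader`, `case_id`, `condition`
#'   (`session1`/`session2`), `value`, with attribute `n_dropped` (named
#'   per-metric count of rows dropped for missing values).
#' @export
build_analysis_table <- function(metrics, pairs) {
  metrics <- tibble::as_tibble(metrics)
  keep <- dplyr::inner_join(metrics, pairs, by = c("reader", "case_id"))
  n_expected <- 2L * nrow(pairs)
  assert_that(nrow(keep) == n_expected,
              sprintf("paired metric rows (%d) do not reconcile with 2 x %d pairs",
                      nrow(keep), nrow(pairs)),
              "cadgaze_reconcile")
  keep$coverage_pct <- 100 * keep$coverage
  long <- tidyr::pivot_longer(
    keep[, c("reader", "session", "case_id", ANALYSIS_METRICS)],
    cols = dplyr::all_of(ANALYSIS_METRICS),
    names_to = "metric", values_to = "value"
  )
  long$condition <- paste0("session", long$session)
  dropped <- dplyr::filter(long, is.na(.data$value))
  long <- dplyr::filter(long, !is.na(.data$value))
  out <- long[, c("metric", "reader", "case_id", "condition", "value")]
  attr(out, "n_dropped") <- table(dropped$metric)
  out
}

#' Fit the condition-contrast linear mixed model for one metric
#'
#' Fits `value ~ condition + (1 | case_id) + (1 | reader)` by REML with
#' session 2 (unprompted) as the reference level, so the fixed effect is
#' the session1 - session2 contrast. The 95% confidence interval and
#' p-value are Wald (normal reference). Variance components estimated at
#' the zero boundary are reported as-is. A response with zero variance is
#' handled as the degenerate limit (all effects and variances zero).
#'
#' @param rows Analysis rows for one metric: `reader`, `case_id`,
#'   `condition` (`session1`/`session2`), `value`.
#' @return An object of class `gaze_lmm`: a list with the fixed-effect
#'   `estimate`, `se`, `ci_lower`, `ci_upper`, `p_value`, the variance
#'   components `var_case`, `var_reader`, `var_resid`, the sizes `n_rows`,
#'   `n_cases`, `n_readers`, the `metric` label (if present in `rows`),
#'   `converged`, and the underlying `lme4` `fit`.
#' @export
fit_condition_lmm <- function(rows) {
  rows <- tibble::as_tibble(rows)
  assert_that(all(c("reader", "case_id", "condition", "value") %in%
                    names(rows)),
              "`rows` needs reader, case_id, condition, value",
              "cadgaze_input")
  conds <- unique(rows$condition)
  assert_that(all(c("session1", "session2") %in% conds),
              "both conditions must be present", "cadgaze_design")
  assert_that(dplyr::n_distinct(rows$reader) >= 2 &&
                dplyr::n_distinct(rows$case_id) >= 2,
              "need at least 2 readers and 2 cases", "cadgaze_design")
  metric <- if ("metric" %in% names(rows)) rows$metric[1] else NA_character_
  rows$condition <- factor(rows$condition,
                           levels = c("session2", "session1"))
  base <- list(metric = metric, n_rows = nrow(rows),
               n_cases = dplyr::n_distinct(rows$case_id),
               n_readers = dplyr::n_distinct(rows$reader),
               inference = "Wald (normal), REML")
  if (stats::var(rows$value) == 0) {
    out <- c(base, list(estimate = 0, se = 0, ci_lower = 0, ci_upper = 0,
                        p_value = 1, var_case = 0, var_reader = 0,
                        var_resid = 0, converged = TRUE, fit = NULL))
    return(structure(out, class = "gaze_lmm"))
  }
  # boundary-fit notes are muffled; variance components are reported anyway
  fit <- suppressMessages(
    lme4::lmer(value ~ condition + (1 | case_id) + (1 | reader),
               data = rows, REML = TRUE)
  )
  msgs <- fit@optinfo$conv$lme4$messages
  # zero-boundary variance components are legitimate, not failures
  msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  converged <- length(msgs) == 0
  est <- lme4::fixef(fit)[["conditionsession1"]]
  se <- sqrt(stats::vcov(fit)["conditionsession1", "conditionsession1"])
  vc <- as.data.frame(lme4::VarCorr(fit))
  getvar <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v) == 0) 0 else v[1]
  }
  z <- stats::qnorm(0.975)
  out <- c(base, list(
    estimate = est, se = se,
    ci_lower = est - z * se, ci_upper = est + z * se,
    p_value = 2 * stats::pnorm(-abs(est / se)),
    var_case = getvar("case_id"), var_reader = getvar("reader"),
    var_resid = getvar("Residual"),
    converged = converged, fit = fit
  ))
  if (!converged) {
    warning("lmer reported convergence issues: ",
            paste(msgs, collapse = "; "))
  }
  structure(out, class = "gaze_lmm")
}

#' @export
print.gaze_lmm <- function(x, ...) {
  cat("<gaze_lmm>", if (!is.na(x$metric)) x$metric else "", "\n")
  cat(sprintf("  session1 - session2: %.4g (95%% CI %.4g to %.4g), p = %.3g\n",
              x$estimate, x$ci_lower, x$ci_upper, x$p_value))
  cat(sprintf("  var: case %.4g, reader %.4g, residual %.4g;  n = %d rows, %d cases, %d readers\n",
              x$var_case, x$var_reader, x$var_resid, x$n_rows, x$n_cases,
              x$n_readers))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the condition contrast of a fitted gaze mixed model
#'
#' @param x A `gaze_lmm`.
#' @param ... Unused.
#' @return A one-row tibble: `metric`, `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `p.value`.
#' @export
tidy.gaze_lmm <- function(x, ...) {
  tibble::tibble(metric = x$metric, term = "conditionsession1",
                 estimate = x$estimate, std.error = x$se,
                 conf.low = x$ci_lower, conf.high = x$ci_upper,
                 p.value = x$p_value)
}

#' Model-level summary of a fitted gaze mixed model
#'
#' @param x A `gaze_lmm`.
#' @param ... Unused.
#' @return A one-row tibble with variance components, sizes, and
#'   convergence status.
#' @export
glance.gaze_lmm <- function(x, ...) {
  tibble::tibble(metric = x$metric, var_case = x$var_case,
                 var_reader = x$var_reader, var_resid = x$var_resid,
                 n_rows = x$n_rows, n_cases = x$n_cases,
                 n_readers = x$n_readers, converged = x$converged)
}

#' Residual diagnostics for a fitted gaze mixed model
#'
#' Advisory checks of the model assumptions on the conditional residuals:
#' a Shapiro-Wilk normality test (on at most 5000 residuals) and the slope
#' of a scale-location regression (sqrt(|standardised residual|) on fitted
#' values; slopes away from zero suggest heteroscedasticity). Diagnostics
#' never alter the fit.
#'
#' @param result A `gaze_lmm` from [fit_condition_lmm()].
#' @return A one-row tibble: `metric`, `shapiro_w`, `shapiro_p`,
#'   `scale_location_slope`, `normality_flag` (p < 0.05), `n`.
#' @export
residual_diagnostics <- function(result) {
  assert_that(inherits(result, "gaze_lmm"), "`result` must be a gaze_lmm",
              "cadgaze_input")
  if (is.null(result$fit)) {
    return(tibble::tibble(metric = result$metric, shapiro_w = NA_real_,
                          shapiro_p = NA_real_,
                          scale_location_slope = NA_real_,
                          normality_flag = NA, n = result$n_rows))
  }
  res <- stats::residuals(result$fit)
  fitted <- stats::fitted(result$fit)
  sub <- if (length(res) > 5000) sample(res, 5000) else res
  sw <- stats::shapiro.test(sub)
  std <- res / stats::sd(res)
  slope <- stats::coef(stats::lm(sqrt(abs(std)) ~ fitted))[[2]]
  tibble::tibble(metric = result$metric, shapiro_w = unname(sw$statistic),
                 shapiro_p = sw$p.value, scale_location_slope = slope,
                 normality_flag = sw$p.value < 0.05, n = length(res))
}

#' Fit the condition model for every metric
#'
#' Runs [fit_condition_lmm()] on each metric of an analysis table and
#' collects tidy results.
#'
#' @param analysis_table Output of [build_analysis_table()].
#' @return A tibble with one row per metric: tidy estimate columns,
#'   variance components, sizes, and a `fit` list-column of `gaze_lmm`
#'   objects.
#' @export
fit_all_metrics <- function(analysis_table) {
  metrics <- unique(analysis_table$metric)
  fits <- lapply(metrics, function(m) {
    fit_condition_lmm(dplyr::filter(analysis_table, .data$metric == m))
  })
  out <- dplyr::bind_rows(lapply(fits, function(f) {
    dplyr::bind_cols(tidy(f), glance(f)[, -1])
  }))
  out$fit <- fits
  out
}

#' Forest-style plot of fitted condition contrasts
#'
#' @param object A tibble from [fit_all_metrics()], or a single
#'   `gaze_lmm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gaze_lmm <- function(object, ...) {
  autoplot_gaze_fits(tidy(object))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# shared forest plot for one or more tidy fit rows
autoplot_gaze_fits <- function(td) {
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$metric)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "session1 - session2 contrast (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot condition contrasts for a set of fitted metrics
#'
#' @param fits A tibble from [fit_all_metrics()].
#' @return A ggplot showing each metric's contrast and 95% CI.
#' @export
plot_condition_effects <- function(fits) {
  autoplot_gaze_fits(fits)
}
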