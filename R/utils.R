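#' @importFrom rlang abort %||%
NULL

# internal: stop with a classed condition so callers/tests can match on class
stop_cadgaze <- function(msg, class) {
  rlang::abort(msg, class = c(class, "cadgaze_error"))
}

assert_that <- function(ok, msg, class = "cadgaze_invalid") {
  if (!isTRUE(ok)) stop_cadgaze(msg, class)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# clamp a numeric vector into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
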