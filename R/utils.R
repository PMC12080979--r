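# Shared internal helpers: timestamp handling, quantiles, error classes.

# All timestamps are timezone-naive local times at minute resolution; they are
# represented internally as POSIXct in UTC so arithmetic is unambiguous.
.parse_minute <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M", tz = "UTC")
}

.format_minute <- function(t) {
  format(t, "%Y-%m-%dT%H:%M", tz = "UTC")
}

.na_time <- function() as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC")

#' Median and interquartile range
#'
#' Summarises a numeric vector by its median and quartiles using linear
#' interpolation between order statistics. The default interpolation rule is
#' the weighted-average convention (`stats::quantile()` type 6, the SPSS
#' default), which the aggregation layer uses throughout; any
#' [stats::quantile()] type can be requested.
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @param quantile_type Interpolation rule passed to [stats::quantile()].
#' @return A named list with `median`, `q1`, `q3` (all `NA` if `x` is empty).
#' @export
#' @examples
#' median_iqr(c(4, 6, 8, 10, 12)) # median 8, IQR (5, 11)
median_iqr <- function(x, quantile_type = 6) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    return(list(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  }
  q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = quantile_type,
                       names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

.abort_schema <- function(msg, ...) {
  rlang::abort(msg, class = "dkaudit_schema_error", ...)
}

.abort_row <- function(msg, ...) {
  rlang::abort(msg, class = "dkaudit_validation_error", ...)
}

.abort_orphan <- function(msg, ...) {
  rlang::abort(msg, class = "dkaudit_orphan_error", ...)
}

.abort_domain <- function(msg, ...) {
  rlang::abort(msg, class = "dkaudit_domain_error", ...)
}

.abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "dkaudit_config_error", ...)
}

.stopifnot_scalar_num <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    .abort_domain(sprintf("`%s` must be a finite numeric scalar.", name))
  }
  if (positive && x <= 0) {
    .abort_domain(sprintf("`%s` must be strictly positive.", name))
  }
  invisible(x)
}
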