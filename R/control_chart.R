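# Moving-median control charts against fixed tolerance limits.

#' Tolerance interval for one parameter
#'
#' The fixed limit pair against which the moving median is judged. In
#' clinical use these come from intra-observer variability studies and are
#' supplied through configuration; they are *not* computed from the data.
#'
#' @param parameter Parameter name.
#' @param lower,upper Limits in the parameter's units, `lower < upper`.
#' @return A `tolerance_interval` object.
#' @export
tolerance_interval <- function(parameter, lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1,
            length(upper) == 1)
  if (!(lower < upper))
    stop("tolerance interval requires lower < upper (got [",
         lower, ", ", upper, "])", call. = FALSE)
  structure(list(parameter = parameter, lower = lower, upper = upper),
            class = "tolerance_interval")
}

#' Trailing moving median
#'
#' The entry at position `i` is the median of `values[(i - window + 1):i]`
#' (right-aligned, inclusive); the first `window - 1` positions are
#' undefined and returned as `NA`. Even windows use the midpoint of the two
#' central order statistics.
#'
#' @param values Numeric vector without missing values.
#' @param window Positive integer window size, at most `length(values)`.
#' @return Numeric vector of `length(values)` with `NA` before the first
#'   full window.
#' @export
moving_median <- function(values, window) {
  if (length(window) != 1 || is.na(window) || window != as.integer(window))
    stop("window must be a single integer", call. = FALSE)
  roll_median_trailing(as.numeric(values), as.integer(window))
}

#' Build a control chart from a cleaned series
#'
#' Computes the trailing moving median over the included values in date
#' order, the center line (global median of all included values) and the
#' alert mask against a tolerance interval. An alert is a defined
#' moving-median entry strictly outside the limits (a value exactly on a
#' limit is in control); set `strict = FALSE` to alert on the limits too.
#'
#' @param series A `parameter_series` from [clean_parameter()], or a plain
#'   data frame with `exam_date`, `value` and optionally `included`.
#' @param window Window size in samples.
#' @param limits A [tolerance_interval()] for the same parameter.
#' @param strict Logical; strict inequality for alerts (default `TRUE`).
#' @return A `control_chart` object: list with `parameter`, `window`,
#'   `dates`, `values` (included values, date order), `mm`, `center`,
#'   `limits`, `alert` (logical, `NA` where `mm` undefined) and `strict`.
#' @export
build_chart <- function(series, window, limits, strict = TRUE) {
  if (!inherits(limits, "tolerance_interval"))
    stop("limits must be a tolerance_interval", call. = FALSE)
  parameter <- attr(series, "parameter") %||% limits$parameter
  keep <- if ("included" %in% names(series)) series$included else TRUE
  dates <- series$exam_date[keep]
  values <- series$value[keep]
  n <- length(values)
  if (n < window)
    stop(sprintf(
      "parameter '%s': %d included values, fewer than window %d",
      parameter, n, window), call. = FALSE)
  mm <- moving_median(values, window)
  alert <- if (strict) mm > limits$upper | mm < limits$lower
           else       mm >= limits$upper | mm <= limits$lower
  structure(list(parameter = parameter, window = as.integer(window),
                 dates = dates, values = values, mm = mm,
                 center = stats::median(values), limits = limits,
                 alert = alert, strict = strict),
            class = "control_chart")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Alert runs of a control chart
#'
#' Groups the alert mask into maximal contiguous runs of out-of-limit
#' moving-median entries. A run never mixes directions: a direct crossing
#' from above the upper limit to below the lower limit between adjacent
#' entries splits the run.
#'
#' @param chart A `control_chart`.
#' @return Data frame with one row per run: `start`, `end` (indices into
#'   the chart's series), `start_date`, `end_date`, `direction` (`"above"`
#'   or `"below"`), `peak` (largest excursion beyond the crossed limit, in
#'   parameter units) and `length`.
#' @export
detect_alerts <- function(chart) {
  stopifnot(inherits(chart, "control_chart"))
  mask <- !is.na(chart$alert) & chart$alert
  dir <- ifelse(chart$mm > chart$limits$upper, "above", "below")
  empty <- data.frame(start = integer(), end = integer(),
                      start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      direction = character(), peak = numeric(),
                      length = integer(), stringsAsFactors = FALSE)
  if (!any(mask)) return(empty)
  idx <- which(mask)
  # split where non-contiguous or direction changes
  brk <- c(TRUE, diff(idx) != 1L | dir[idx[-1]] != dir[idx[-length(idx)]])
  grp <- cumsum(brk)
  runs <- lapply(split(idx, grp), function(ix) {
    d <- dir[ix[1]]
    exc <- if (d == "above") max(chart$mm[ix]) - chart$limits$upper
           else chart$limits$lower - min(chart$mm[ix])
    data.frame(start = ix[1], end = ix[length(ix)],
               start_date = chart$dates[ix[1]],
               end_date = chart$dates[ix[length(ix)]],
               direction = d, peak = exc, length = length(ix),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  out
}

#' Default reporting periods
#'
#' @param split Date splitting the record into an early and a late period.
#' @return Named list of `c(from, to)` date pairs.
#' @export
default_periods <- function(split = as.Date("2013-01-01")) {
  list(before = c(as.Date("1900-01-01"), split - 1),
       after  = c(split, as.Date("2999-12-31")))
}

#' Aggregate alerts to percentages per year and per period
#'
#' For each calendar year, the percentage of *defined* moving-median
#' entries dated in that year that are alerts; each examination past the
#' warm-up contributes exactly one entry, so this equals the percentage of
#' examinations crossing the limits. Period values are arithmetic means of
#' the constituent per-year percentages. Years with no defined entries are
#' omitted; a period covering no represented year is dropped with a
#' warning.
#'
#' @param chart A `control_chart`.
#' @param periods Named list of `c(from, to)` `Date` pairs
#'   (default: [default_periods()]). Must be disjoint.
#' @return An `alert_summary`: list with `parameter`, `window`, `per_year`
#'   (named numeric, percent) and `per_period` (named numeric, percent).
#' @export
aggregate_alerts <- function(chart, periods = default_periods()) {
  stopifnot(inherits(chart, "control_chart"))
  def <- !is.na(chart$alert)
  years <- as.integer(format(chart$dates[def], "%Y"))
  alerts <- chart$alert[def]
  per_year <- 100 * tapply(alerts, years, mean)
  per_year <- per_year[order(as.integer(names(per_year)))]

  yr <- as.integer(names(per_year))
  per_period <- vapply(names(periods), function(nm) {
    rng <- periods[[nm]]
    from_y <- as.integer(format(rng[1], "%Y"))
    to_y <- as.integer(format(rng[2], "%Y"))
    in_p <- yr >= from_y & yr <= to_y
    if (!any(in_p)) return(NA_real_)
    mean(per_year[in_p])
  }, numeric(1))
  if (anyNA(per_period)) {
    warning("period(s) with no represented years omitted: ",
            paste(names(per_period)[is.na(per_period)], collapse = ", "),
            call. = FALSE)
    per_period <- per_period[!is.na(per_period)]
  }
  structure(list(parameter = chart$parameter, window = chart$window,
                 per_year = per_year, per_period = per_period),
            class = "alert_summary")
}

#' @export
print.control_chart <- function(x, ...) {
  n_def <- sum(!is.na(x$mm))
  n_alert <- sum(x$alert, na.rm = TRUE)
  cat(sprintf(
    "Control chart '%s' (window %d): %d entries, %d defined MM, %d alerts\n",
    x$parameter, x$window, length(x$values), n_def, n_alert))
  cat(sprintf("  center %.4g, limits [%.4g, %.4g]\n",
              x$center, x$limits$lower, x$limits$upper))
  invisible(x)
}

#' @export
print.alert_summary <- function(x, ...) {
  cat(sprintf("Alerts per year for '%s' (window %d):\n", x$parameter,
              x$window))
  print(round(x$per_year, 2))
  cat("Period means:\n")
  print(round(x$per_period, 2))
  invisible(x)
}

#' Export a chart as a tidy data frame (one row per included examination)
#'
#' @param chart A `control_chart`.
#' @return Data frame with `date`, `value`, `mm`, `in_control` (`NA` during
#'   warm-up).
#' @export
chart_frame <- function(chart) {
  data.frame(date = chart$dates, value = chart$values, mm = chart$mm,
             in_control = !chart$alert)
}
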