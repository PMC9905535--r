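# Synthetic phantom: bimodal sex-mixture stream and step-bias injection.

#' Phantom configuration
#'
#' Describes a stationary stream of synthetic parameter values drawn i.i.d.
#' from a normal mixture, with synthetic exam dates assigned at a fixed
#' number of examinations per calendar month.
#'
#' @param components Data frame with columns `weight`, `mean`, `sd`, one
#'   row per mixture component. Weights must sum to 1; sds must be
#'   positive.
#' @param n_samples Number of samples to draw.
#' @param seed Integer seed making the stream reproducible.
#' @param start_date First exam date.
#' @param exams_per_month Examinations assigned to each calendar month.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(components, n_samples = 20000L, seed = 20337L,
                           start_date = as.Date("2010-03-01"),
                           exams_per_month = 197L) {
  components <- as.data.frame(components)
  stopifnot(all(c("weight", "mean", "sd") %in% names(components)),
            n_samples >= 1, exams_per_month >= 1)
  if (abs(sum(components$weight) - 1) > 1e-8)
    stop("component weights must sum to 1", call. = FALSE)
  if (any(components$sd < 0))
    stop("component sds must be nonnegative", call. = FALSE)
  structure(list(components = components, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), start_date = as.Date(start_date),
                 exams_per_month = as.integer(exams_per_month)),
            class = "phantom_config")
}

#' Default phantom: sex-stratified LV stroke volume mixture
#'
#' Two normal components parameterized from the sex-stratified LV SV
#' summary statistics of a large clinical CMR cohort: females
#' N(75.5, 18.1^2), males N(93.9, 25.5^2), weighted by the cohort's sex
#' counts 8553 and 11784 (the exact mixture behind the published phantom
#' figures is not printed; this parameterization is a documented modeling
#' choice, not a transcription). 20,000 samples, roughly the size of the
#' cohort, at 197 examinations per month.
#'
#' @param n_samples Number of samples (default 20,000).
#' @param seed Seed (default 20337, the documented package default).
#' @return A `phantom_config`.
#' @export
default_phantom_config <- function(n_samples = 20000L, seed = 20337L) {
  phantom_config(
    components = data.frame(
      weight = c(8553, 11784) / (8553 + 11784),
      mean = c(75.5, 93.9),
      sd = c(18.1, 25.5),
      row.names = c("f", "m")),
    n_samples = n_samples, seed = seed)
}

#' Closed-form moments and median of the mixture
#'
#' Mean is \eqn{\sum w_i \mu_i}; variance is
#' \eqn{\sum w_i (\sigma_i^2 + \mu_i^2) - \mu^2}. The median solves
#' \eqn{\sum w_i \Phi((x - \mu_i)/\sigma_i) = 1/2} and is found
#' numerically.
#'
#' @param config A `phantom_config`.
#' @return List with `mean`, `sd`, `median`.
#' @export
mixture_stats <- function(config) {
  co <- config$components
  m <- sum(co$weight * co$mean)
  v <- sum(co$weight * (co$sd^2 + co$mean^2)) - m^2
  cdf <- function(x) sum(co$weight * stats::pnorm(x, co$mean, co$sd)) - 0.5
  lo <- min(co$mean - 6 * pmax(co$sd, 1e-12))
  hi <- max(co$mean + 6 * pmax(co$sd, 1e-12))
  med <- if (hi > lo) stats::uniroot(cdf, c(lo, hi), tol = 1e-10)$root
         else co$mean[1]
  list(mean = m, sd = sqrt(v), median = med)
}

# Sequential synthetic dates: exams_per_month per calendar month, spread
# evenly across the month's days.
phantom_dates <- function(n, start_date, exams_per_month) {
  month_idx <- (seq_len(n) - 1L) %/% exams_per_month
  months <- seq(as.Date(format(start_date, "%Y-%m-01")), by = "month",
                length.out = max(month_idx) + 2L)
  pos <- (seq_len(n) - 1L) %% exams_per_month
  first <- months[month_idx + 1L]
  ndays <- as.integer(months[month_idx + 2L] - first)
  first + floor(pos / exams_per_month * ndays)
}

#' Draw a stationary phantom series
#'
#' Independent draws from the mixture: a component is chosen per the
#' weights, then a normal variate is drawn; there is no dependence on the
#' time component, so the stream is drift-free by construction. Dates are
#' synthetic plumbing for the calendar-based reporting functions.
#'
#' @param config A `phantom_config`.
#' @return A `parameter_series` data frame (`exam_date`, `value`,
#'   `included`, `reason`) with an extra `component` column and attributes
#'   `parameter = "sv"` and `seed`.
#' @export
sample_bimodal <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  co <- config$components
  n <- config$n_samples
  comp <- sample.int(nrow(co), n, replace = TRUE, prob = co$weight)
  values <- stats::rnorm(n, mean = co$mean[comp], sd = co$sd[comp])
  out <- data.frame(
    exam_date = phantom_dates(n, config$start_date, config$exams_per_month),
    value = values,
    included = TRUE,
    reason = NA_character_,
    component = comp,
    stringsAsFactors = FALSE)
  attr(out, "parameter") <- "sv"
  attr(out, "seed") <- config$seed
  class(out) <- c("parameter_series", class(out))
  out
}

#' Step-bias description
#'
#' A constant offset added to every value from `onset` (1-based index of
#' the first distorted sample) onward — the time-discrete distortion a
#' confounding event introduces into the measurement chain.
#'
#' @param onset 1-based index of the first shifted sample.
#' @param magnitude Offset in parameter units (ml for volumes).
#' @param kind Only `"step"` is implemented.
#' @return A `drift_spec` object.
#' @export
drift_spec <- function(onset, magnitude, kind = "step") {
  kind <- match.arg(kind)
  stopifnot(length(onset) == 1, onset == as.integer(onset), onset >= 1)
  structure(list(kind = kind, onset = as.integer(onset),
                 magnitude = magnitude), class = "drift_spec")
}

#' Inject a step bias into a series
#'
#' Adds `spec$magnitude` to every value at index `>= spec$onset`; all other
#' values and all dates are unchanged. Also returns the matching confounder
#' indicator (0 before onset, 1 from onset onward).
#'
#' @param series A `parameter_series` (or data frame with `value`).
#' @param spec A [drift_spec()].
#' @return List with `series` (shifted copy) and `confounder` (integer
#'   0/1 vector).
#' @export
inject_step <- function(series, spec) {
  stopifnot(inherits(spec, "drift_spec"))
  n <- nrow(series)
  if (spec$onset > n)
    stop("drift onset (", spec$onset, ") outside series of length ", n,
         call. = FALSE)
  shifted <- series
  ix <- seq_len(n) >= spec$onset
  shifted$value[ix] <- shifted$value[ix] + spec$magnitude
  attr(shifted, "drift") <- spec
  list(series = shifted, confounder = as.integer(ix))
}

#' Emit a phantom stream in the exam-table CSV dialect
#'
#' Writes the synthetic series as an exam-report table readable by
#' [read_exam_table()], so the full cleaning/charting pipeline runs
#' end-to-end on synthetic data. The mixture component is exported as the
#' sex column (component 1 = f, 2 = m); only the `sv` measurement column is
#' populated. An optional confounder indicator is written as a parallel
#' column.
#'
#' @param series A `parameter_series` from [sample_bimodal()].
#' @param path Output CSV path.
#' @param confounder Optional 0/1 vector from [inject_step()].
#' @return `path`, invisibly.
#' @export
write_phantom_csv <- function(series, path, confounder = NULL) {
  out <- data.frame(
    exam_date = format(series$exam_date, "%Y-%m-%d"),
    age = NA_real_, weight = NA_real_, height = NA_real_,
    sex = c("f", "m")[series$component %||% rep(1L, nrow(series))],
    ef = NA_real_, edv = NA_real_, sv = series$value, lvm = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(confounder)) out$confounder <- confounder
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
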