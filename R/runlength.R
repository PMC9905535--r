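# Monte-Carlo operating characteristics of the moving-median chart:
# Average Run Length (in control) and Average Delay Time (after a step).
#
# Run lengths are measured in samples (examinations); reports may convert
# to months via exams_per_month. Seeds are per-replicate (base seed + rep),
# so two calls with the same seed see the same stationary streams --
# common random numbers for paired comparisons across windows/limits.

rep_config <- function(config, n, seed) {
  phantom_config(config$components, n_samples = n, seed = seed,
                 start_date = config$start_date,
                 exams_per_month = config$exams_per_month)
}

summarise_runs <- function(metric, rl, n_reps, window, limits, drift,
                           extra = list()) {
  ok <- !is.na(rl)
  structure(c(list(
    metric = metric, window = window, limits = limits, drift = drift,
    n_reps = n_reps,
    mean = if (any(ok)) mean(rl[ok]) else NA_real_,
    sd = if (sum(ok) > 1) stats::sd(rl[ok]) else NA_real_,
    censored_fraction = mean(!ok),
    run_lengths = rl), extra),
    class = "run_length_estimate")
}

#' Average Run Length of the in-control chart
#'
#' Per replicate, draws a stationary phantom stream, builds the chart and
#' records the index of the first alert among the defined moving-median
#' entries (1 = the first defined entry alerts). Replicates with no alert
#' before the stream ends are censored: they are counted, never imputed,
#' so short streams bias the mean visibly rather than silently.
#'
#' @param config A `phantom_config` (its `seed` is ignored; see `seed`).
#' @param window Window size in samples.
#' @param limits A [tolerance_interval()].
#' @param n_reps Number of Monte-Carlo replicates.
#' @param max_len Stream length per replicate (default: the config's
#'   `n_samples`).
#' @param seed Base seed; replicate r uses `seed + r - 1`.
#' @return A `run_length_estimate`: `metric = "ARL"`, `mean`, `sd` over
#'   uncensored replicates, `censored_fraction`, and the per-replicate
#'   `run_lengths` (`NA` = censored).
#' @export
estimate_arl <- function(config, window, limits, n_reps = 100L,
                         max_len = config$n_samples, seed = 1L) {
  stopifnot(inherits(config, "phantom_config"), max_len > window,
            n_reps >= 1)
  ms <- mixture_stats(config)
  if (limits$lower > ms$median || limits$upper < ms$median)
    warning("tolerance interval does not bracket the mixture median; ",
            "the ARL will be trivially small", call. = FALSE)
  rl <- vapply(seq_len(n_reps), function(r) {
    s <- sample_bimodal(rep_config(config, max_len, seed + r - 1L))
    ch <- build_chart(s, window, limits)
    first <- which(ch$alert)[1]
    if (is.na(first)) NA_real_ else first - window + 1
  }, numeric(1))
  summarise_runs("ARL", rl, n_reps, window, limits, drift = NULL)
}

#' Average Delay Time after a step bias
#'
#' Per replicate, draws a stationary stream, injects the step, builds the
#' chart, and records the delay from onset to the first alert at or after
#' onset (`0` = the entry at the onset sample alerts). Replicates that
#' alert *before* onset are false-alert contaminated: they are discarded
#' from the mean and reported via `false_alert_fraction`. Replicates with
#' no post-onset alert are censored.
#'
#' @inheritParams estimate_arl
#' @param drift A [drift_spec()] with nonzero magnitude; the onset must
#'   leave at least `2 * window` post-onset samples.
#' @return A `run_length_estimate` with `metric = "ADT"` and an additional
#'   `false_alert_fraction`.
#' @export
estimate_adt <- function(config, drift, window, limits, n_reps = 100L,
                         seed = 1L) {
  stopifnot(inherits(config, "phantom_config"), inherits(drift, "drift_spec"))
  if (drift$magnitude == 0)
    stop("ADT is undefined without a bias (magnitude = 0)", call. = FALSE)
  n <- config$n_samples
  if (n - drift$onset + 1L < 2L * window)
    stop("drift onset must leave at least 2 x window post-onset samples",
         call. = FALSE)
  ms <- mixture_stats(config)
  if (limits$lower > ms$median || limits$upper < ms$median)
    warning("tolerance interval does not bracket the mixture median",
            call. = FALSE)
  false_alert <- logical(n_reps)
  rl <- vapply(seq_len(n_reps), function(r) {
    s <- sample_bimodal(rep_config(config, n, seed + r - 1L))
    sh <- inject_step(s, drift)$series
    ch <- build_chart(sh, window, limits)
    alerts <- which(ch$alert)
    if (length(alerts) && alerts[1] < drift$onset) {
      false_alert[r] <<- TRUE
      return(NA_real_)
    }
    first <- alerts[alerts >= drift$onset][1]
    if (is.na(first)) NA_real_ else first - drift$onset
  }, numeric(1))
  est <- summarise_runs("ADT", rl, n_reps, window, limits, drift,
                        extra = list(false_alert_fraction = mean(false_alert)))
  # censored = neither false-alerted nor alerted after onset
  est$censored_fraction <- mean(is.na(rl) & !false_alert)
  est
}

#' @export
print.run_length_estimate <- function(x, ...) {
  cat(sprintf(
    "%s (window %d, limits [%.4g, %.4g]): mean %.1f, sd %.1f over %d reps (%.0f%% censored)\n",
    x$metric, x$window, x$limits$lower, x$limits$upper,
    x$mean, x$sd, x$n_reps, 100 * x$censored_fraction))
  invisible(x)
}

#' ARL/ADT surface over a grid of windows, limit half-widths and magnitudes
#'
#' Runs [estimate_arl()] for every window x half-width combination and
#' [estimate_adt()] additionally for every magnitude, with common random
#' numbers (the same base seed) across all cells so that comparisons along
#' any axis are paired. Limits are centered on the mixture median.
#'
#' @param config A `phantom_config`.
#' @param windows Integer vector of window sizes.
#' @param half_widths Numeric vector of limit half-widths (parameter
#'   units).
#' @param magnitudes Numeric vector of step magnitudes for ADT (use
#'   `numeric(0)` to skip ADT).
#' @param onset Step onset for ADT (default: middle of the stream).
#' @param n_reps Replicates per cell.
#' @param seed Base seed shared by every cell.
#' @return Tidy data frame: `metric`, `window`, `half_width`, `magnitude`
#'   (`NA` for ARL rows), `mean`, `sd`, `censored_fraction`,
#'   `false_alert_fraction`, `n_reps`.
#' @export
run_length_grid <- function(config, windows = c(250L, 750L),
                            half_widths = 3, magnitudes = 5,
                            onset = config$n_samples %/% 2L + 1L,
                            n_reps = 50L, seed = 1L) {
  med <- mixture_stats(config)$median
  rows <- list()
  for (hw in half_widths) {
    lim <- tolerance_interval("sv", med - hw, med + hw)
    for (w in windows) {
      a <- estimate_arl(config, w, lim, n_reps = n_reps, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = "ARL", window = w, half_width = hw, magnitude = NA_real_,
        mean = a$mean, sd = a$sd, censored_fraction = a$censored_fraction,
        false_alert_fraction = NA_real_, n_reps = n_reps)
      for (mg in magnitudes) {
        d <- estimate_adt(config, drift_spec(onset, mg), w, lim,
                          n_reps = n_reps, seed = seed)
        rows[[length(rows) + 1L]] <- data.frame(
          metric = "ADT", window = w, half_width = hw, magnitude = mg,
          mean = d$mean, sd = d$sd, censored_fraction = d$censored_fraction,
          false_alert_fraction = d$false_alert_fraction, n_reps = n_reps)
      }
    }
  }
  do.call(rbind, rows)
}

#' Constrained window pick from a run-length grid (extension)
#'
#' A simple selection heuristic layered on the ARL/ADT surfaces, not part
#' of the monitoring procedure itself: among the windows whose mean ADT
#' stays below a user ceiling, pick the largest (strongest noise
#' suppression, hence longest ARL).
#'
#' @param grid Output of [run_length_grid()].
#' @param adt_ceiling Largest acceptable mean delay (samples).
#' @return The chosen window size, or `NA` if no window qualifies.
#' @export
pick_window <- function(grid, adt_ceiling) {
  adt <- grid[grid$metric == "ADT" & !is.na(grid$mean), ]
  ok <- tapply(adt$mean <= adt_ceiling, adt$window, all)
  w <- as.integer(names(ok))[ok]
  if (!length(w)) NA_integer_ else max(w)
}
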