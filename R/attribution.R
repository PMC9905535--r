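# Drift attribution: Granger causality against candidate confounders and
# step-magnitude recovery from the moving-median curve.

lags_of <- function(x, L, from) {
  # matrix with rows t = from..length(x), columns x[t-1], ..., x[t-L]
  n <- length(x)
  vapply(seq_len(L), function(k) x[(from:n) - k], numeric(n - from + 1))
}

#' Granger causality test (bivariate, lagged-regression F-test)
#'
#' Tests whether the lags of `cause` improve the prediction of `effect`
#' beyond the lags of `effect` itself. The restricted model regresses
#' `effect_t` on its own lags `1..L`; the unrestricted model adds the
#' lags `1..L` of `cause`; the F-test compares the two. The direction is
#' asymmetric: only cause -> effect is tested, and the reverse direction is
#' an independent second call.
#'
#' When `lag` is `NULL`, `L` is the minimizer of the AIC of the
#' *restricted* autoregression of the effect over `1..max_lag`, all
#' candidates fitted on the same observations (those with `max_lag`
#' available lags); the final models are then refitted at the chosen `L`
#' on every observation with `L` available lags. Selecting the lag without
#' looking at the cause's lags keeps the subsequent F-test honest: picking
#' the order that makes the cause look best inflates the false-positive
#' rate well beyond the nominal level.
#'
#' The test assumes stationarity; a deterministic step in either series
#' violates it. The test is still computed — mirroring the intended use of
#' confronting a step-indicator confounder with the raw examination stream
#' — but a warning is issued for monotone (step-like) inputs rather than
#' differencing silently. Set `difference = TRUE` to first-difference both
#' series instead.
#'
#' @param cause Numeric candidate-cause series (e.g. a 0/1 confounder
#'   indicator).
#' @param effect Numeric effect series (the raw per-exam parameter values;
#'   moving-median values are strongly autocorrelated by construction and
#'   should not be fed to this test).
#' @param max_lag Largest lag order considered (default 5).
#' @param lag Fixed lag order, bypassing AIC selection.
#' @param difference First-difference both series before testing.
#' @return A `granger_result`: list with `cause`, `effect` (deparsed
#'   names), `lag`, `f_stat`, `p_value`, `n_obs` and `aic` (per-lag AIC of
#'   the unrestricted model, when selected).
#' @export
granger_test <- function(cause, effect, max_lag = 5L, lag = NULL,
                         difference = FALSE) {
  cause_name <- deparse1(substitute(cause))
  effect_name <- deparse1(substitute(effect))
  cause <- as.numeric(cause); effect <- as.numeric(effect)
  if (length(cause) != length(effect))
    stop("cause and effect series must have equal length", call. = FALSE)
  if (anyNA(cause) || anyNA(effect))
    stop("series must not contain missing values", call. = FALSE)
  L_max <- if (is.null(lag)) as.integer(max_lag) else as.integer(lag)
  if (L_max < 1) stop("lag order must be >= 1", call. = FALSE)
  if (length(effect) <= 3L * L_max + 2L)
    stop("series too short for lag order ", L_max, call. = FALSE)
  if (difference) {
    cause <- diff(cause); effect <- diff(effect)
  }
  if (stats::sd(effect) == 0)
    stop("effect series is constant; regression is degenerate",
         call. = FALSE)
  mono <- function(x) all(diff(x) >= 0) || all(diff(x) <= 0)
  if (!difference && (mono(cause) || mono(effect)))
    warning("monotone (step-like) input violates the stationarity ",
            "assumption of the Granger test; interpret the p-value as a ",
            "descriptive screen", call. = FALSE)

  n <- length(effect)
  aic <- NULL
  if (is.null(lag)) {
    from <- L_max + 1L  # common sample across candidate lags
    y <- effect[from:n]
    aic <- vapply(seq_len(L_max), function(L) {
      stats::AIC(stats::lm(y ~ lags_of(effect, L, from)))
    }, numeric(1))
    L <- which.min(aic)
  } else L <- as.integer(lag)

  from <- L + 1L
  y <- effect[from:n]
  Xe <- lags_of(effect, L, from)
  Xc <- lags_of(cause, L, from)
  restricted <- stats::lm(y ~ Xe)
  unrestricted <- stats::lm(y ~ Xe + Xc)
  cmp <- stats::anova(restricted, unrestricted)
  structure(list(cause = cause_name, effect = effect_name, lag = L,
                 f_stat = cmp$F[2], p_value = cmp$`Pr(>F)`[2],
                 n_obs = length(y), aic = aic),
            class = "granger_result")
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf(
    "Granger test %s -> %s: lag %d, F = %.4g, p = %.4g (n = %d)\n",
    x$cause, x$effect, x$lag, x$f_stat, x$p_value, x$n_obs))
  invisible(x)
}

#' Step-indicator series from an event calendar
#'
#' For each dated event (staff rotation, scanner relocation, software
#' update, ...), builds the 0/1 indicator aligned to the exam stream: 0
#' before the event date, 1 from the first examination on or after it.
#'
#' @param dates Exam dates of the stream, nondecreasing.
#' @param events Named list or vector of event dates, or a data frame with
#'   columns `name` and `date`.
#' @return Integer matrix, one column per event.
#' @export
events_to_indicator <- function(dates, events) {
  if (is.data.frame(events)) {
    ev <- as.Date(events$date); names(ev) <- events$name
  } else {
    ev <- as.Date(unlist(events, use.names = FALSE))
    names(ev) <- names(events) %||% paste0("event", seq_along(ev))
  }
  out <- vapply(ev, function(d) as.integer(dates >= d),
                integer(length(dates)))
  colnames(out) <- names(ev)
  out
}

#' Recover a step change from the moving-median curve
#'
#' Quantifies the drift a step bias leaves in a moving-median chart. The
#' pre-change level is the median of moving-median entries whose windows
#' end at least one full window before onset, the post-change level the
#' median of entries whose windows start at or after onset; entries whose
#' windows straddle the onset mix both distributions and are excluded from
#' both levels. When `onset` is not supplied it is estimated in two
#' stages: a global split search maximizing the between-segment median
#' difference scaled by the split's precision (`|d| / sqrt(1/n_pre +
#' 1/n_post)`; unscaled, the argmax drifts toward the series edges where
#' segment medians are noisy), followed by a local refinement within one
#' window of the split using the moving-median jump
#' `J(s) = mm[s + w - 1] - mm[s - 1]`, taking the midpoint of the maximal
#' plateau of `|J|`. For a noiseless step the plateau of the saturated
#' median jump is symmetric about the true onset, so the refinement
#' recovers the onset sample exactly; in noise the onset uncertainty is of
#' the order of the window.
#'
#' @param chart A `control_chart`.
#' @param onset Optional known 1-based onset index (first changed sample).
#' @param search_range Optional `c(from, to)` index range for the onset
#'   search.
#' @return A `step_estimate`: list with `onset_estimate`,
#'   `magnitude_estimate` (= `post_level - pre_level`), `pre_level`,
#'   `post_level`, `n_pre`, `n_post`.
#' @export
estimate_step <- function(chart, onset = NULL, search_range = NULL) {
  stopifnot(inherits(chart, "control_chart"))
  w <- chart$window
  mm <- chart$mm
  n <- length(mm)
  defined <- which(!is.na(mm))
  if (length(defined) < 3L * w)
    stop("need at least 3 x window defined moving-median entries (have ",
         length(defined), ")", call. = FALSE)

  scaled_split <- function(s) {
    pre <- mm[defined[defined <= s - w]]
    post <- mm[defined[defined >= s + w - 1L]]
    if (!length(pre) || !length(post)) return(NA_real_)
    d <- stats::median(post) - stats::median(pre)
    d / sqrt(1 / length(pre) + 1 / length(post))
  }

  if (is.null(onset)) {
    # stage 1: global split, candidates keeping at least one full window
    # of defined entries on each side
    lo <- max(3L * w - 1L, if (!is.null(search_range)) search_range[1] else 0L)
    hi <- min(n - 2L * w + 2L,
              if (!is.null(search_range)) search_range[2] else n)
    if (hi < lo) stop("empty onset search range", call. = FALSE)
    by <- max(1L, (hi - lo) %/% 1024L)
    cand <- seq.int(lo, hi, by = by)
    split <- cand[which.max(abs(vapply(cand, scaled_split, numeric(1))))]
    if (by > 1L) {
      cand <- seq.int(max(lo, split - by), min(hi, split + by))
      split <- cand[which.max(abs(vapply(cand, scaled_split, numeric(1))))]
    }
    # stage 2: refine by the local moving-median jump around the split
    cand <- seq.int(max(w + 1L, split - w), min(n - w + 1L, split + w))
    jump <- mm[cand + w - 1L] - mm[cand - 1L]
    peak <- which.max(abs(jump))
    top <- abs(jump) == abs(jump[peak])
    a <- peak; while (a > 1L && top[a - 1L]) a <- a - 1L
    b <- peak; while (b < length(top) && top[b + 1L]) b <- b + 1L
    onset <- cand[(a + b) %/% 2L]
  }

  pre_ix <- defined[defined <= onset - w]
  post_ix <- defined[defined >= onset + w - 1L]
  if (length(pre_ix) < 1L || length(post_ix) < 1L)
    stop("too few fully-pre or fully-post moving-median entries around ",
         "onset ", onset, call. = FALSE)
  pre <- stats::median(mm[pre_ix])
  post <- stats::median(mm[post_ix])
  structure(list(onset_estimate = as.integer(onset),
                 magnitude_estimate = post - pre,
                 pre_level = pre, post_level = post,
                 n_pre = length(pre_ix), n_post = length(post_ix)),
            class = "step_estimate")
}

#' @export
print.step_estimate <- function(x, ...) {
  cat(sprintf(
    "Step estimate: onset %d, magnitude %.4g (pre %.4g -> post %.4g; n = %d/%d)\n",
    x$onset_estimate, x$magnitude_estimate, x$pre_level, x$post_level,
    x$n_pre, x$n_post))
  invisible(x)
}
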