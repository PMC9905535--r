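# End-to-end pipeline: ingest -> clean -> derive -> chart -> alerts ->
# aggregation -> optional attribution, with a machine-readable manifest.

#' Assemble a pipeline configuration
#'
#' Either `input` (an exam-table CSV) or `phantom` (a [phantom_config()],
#' optionally with `drift`) must be given. Every parameter to be charted
#' needs a tolerance interval.
#'
#' @param input Path to an exam-table CSV, or `NULL`.
#' @param phantom A `phantom_config`, or `NULL`.
#' @param drift Optional [drift_spec()] applied to the phantom stream.
#' @param parameters Parameters to clean and chart.
#' @param windows Moving-median window sizes (default `c(250, 750)`).
#' @param limits Named list of `c(lower, upper)` pairs, one per charted
#'   parameter.
#' @param periods Named list of date ranges for alert aggregation.
#' @param events Optional data frame (`name`, `date`) of confounder events
#'   for attribution and figure bands.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest and used for phantom
#'   generation.
#' @param column_map Column mapping for `input`.
#' @param figures Render PNG figures (default `FALSE`; all numeric
#'   artifacts are CSV/JSON regardless).
#' @param granger Run the Granger attribution when a confounder indicator
#'   is available (phantom with drift, or `events`).
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, phantom = NULL, drift = NULL,
                       parameters = "sv", windows = c(250L, 750L),
                       limits = list(), periods = default_periods(),
                       events = NULL, out_dir = tempfile("cmrqc_run_"),
                       seed = 20337L, column_map = default_column_map(),
                       figures = FALSE, granger = TRUE) {
  if (is.null(input) && is.null(phantom))
    stop("either an input CSV or a phantom config is required",
         call. = FALSE)
  missing_limits <- setdiff(parameters, names(limits))
  if (length(missing_limits))
    stop("no tolerance limits supplied for parameter(s): ",
         paste(missing_limits, collapse = ", "), call. = FALSE)
  structure(list(input = input, phantom = phantom, drift = drift,
                 parameters = parameters, windows = as.integer(windows),
                 limits = limits, periods = periods, events = events,
                 out_dir = out_dir, seed = as.integer(seed),
                 column_map = column_map, figures = figures,
                 granger = granger),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields mirror [run_config()]; `limits` is a mapping parameter ->
#' `{lower, upper}`, `phantom` a mapping with `components` (list of
#' `{weight, mean, sd}`), `n_samples`, `seed`, and `drift` a mapping with
#' `onset` and `magnitude`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  phantom <- NULL
  if (!is.null(y$phantom)) {
    comp <- do.call(rbind, lapply(y$phantom$components, as.data.frame))
    phantom <- phantom_config(
      comp,
      n_samples = y$phantom$n_samples %||% 20000L,
      seed = y$phantom$seed %||% y$seed %||% 20337L,
      exams_per_month = y$phantom$exams_per_month %||% 197L)
  }
  drift <- if (!is.null(y$drift))
    drift_spec(y$drift$onset, y$drift$magnitude)
  limits <- lapply(y$limits, function(l) c(l$lower, l$upper))
  run_config(input = y$input, phantom = phantom, drift = drift,
             parameters = y$parameters %||% "sv",
             windows = unlist(y$windows) %||% c(250L, 750L),
             limits = limits,
             out_dir = y$out_dir %||% tempfile("cmrqc_run_"),
             seed = y$seed %||% 20337L,
             figures = isTRUE(y$figures))
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  path
}

#' Run the full quality-control pipeline
#'
#' Executes clean -> derive -> chart (per parameter x window) -> alert
#' detection -> per-year aggregation -> optional Granger attribution, and
#' writes every artifact (tidy CSVs, JSON summaries, optional figures)
#' under `config$out_dir` together with a manifest listing each file, the
#' seed and an MD5 hash of the configuration. Identical configuration and
#' seed reproduce every numeric artifact byte for byte.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly: list with `files`, `seed`,
#'   `config_hash`, `alert_runs` (total count), `stages`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(path) files[length(files) + 1L] <<- path
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  confounder <- NULL
  records <- stage("ingest", {
    if (!is.null(config$input)) {
      read_exam_table(config$input, config$column_map)
    } else {
      ph <- config$phantom
      ph$seed <- config$seed
      s <- sample_bimodal(ph)
      if (!is.null(config$drift)) {
        inj <- inject_step(s, config$drift)
        s <- inj$series
        confounder <- inj$confounder
      }
      tmp <- file.path(config$out_dir, "phantom_input.csv")
      write_phantom_csv(s, tmp, confounder)
      emit(tmp)
      read_exam_table(tmp)
    }
  })

  total_runs <- 0L
  stages_run <- c("ingest")
  for (p in config$parameters) {
    cl <- stage(paste0("clean:", p), clean_parameter(records, p))
    f <- file.path(config$out_dir, sprintf("cleaned_%s.csv", p))
    write_series_csv(cl$series, f); emit(f)
    f <- file.path(config$out_dir, sprintf("cleaning_report_%s.json", p))
    write_json_artifact(unclass(cl$report), f); emit(f)

    lim <- tolerance_interval(p, config$limits[[p]][1], config$limits[[p]][2])
    for (w in config$windows) {
      ch <- stage(sprintf("chart:%s:w%d", p, w),
                  build_chart(cl$series, w, lim))
      f <- file.path(config$out_dir, sprintf("chart_%s_w%d.csv", p, w))
      utils::write.csv(chart_frame(ch), f, row.names = FALSE, quote = FALSE,
                       na = ""); emit(f)
      runs <- detect_alerts(ch)
      total_runs <- total_runs + nrow(runs)
      f <- file.path(config$out_dir, sprintf("alerts_%s_w%d.csv", p, w))
      utils::write.csv(runs, f, row.names = FALSE, quote = FALSE, na = "")
      emit(f)
      summ <- suppressWarnings(aggregate_alerts(ch, config$periods))
      f <- file.path(config$out_dir, sprintf("alert_summary_%s_w%d.json", p, w))
      write_json_artifact(list(parameter = p, window = w,
                               per_year = as.list(summ$per_year),
                               per_period = as.list(summ$per_period)), f)
      emit(f)
      if (isTRUE(config$figures)) {
        f <- file.path(config$out_dir, sprintf("chart_%s_w%d.png", p, w))
        render_chart(ch, events = config$events, file = f); emit(f)
      }
      stages_run <- c(stages_run, sprintf("chart:%s:w%d", p, w))
    }

    if (isTRUE(config$granger)) {
      raw <- cl$series$value[cl$series$included]
      ind <- if (!is.null(confounder)) {
        confounder[cl$series$included]
      } else if (!is.null(config$events)) {
        events_to_indicator(cl$series$exam_date[cl$series$included],
                            config$events)[, 1]
      } else NULL
      if (!is.null(ind) && stats::sd(ind) > 0) {
        g <- stage(paste0("granger:", p),
                   suppressWarnings(granger_test(ind, raw)))
        f <- file.path(config$out_dir, sprintf("granger_%s.json", p))
        write_json_artifact(unclass(g), f); emit(f)
        stages_run <- c(stages_run, paste0("granger:", p))
      }
    }
  }

  cfg_file <- file.path(config$out_dir, "config.json")
  cfg_serializable <- config
  cfg_serializable$phantom <- if (!is.null(config$phantom))
    c(unclass(config$phantom)["components"],
      lapply(unclass(config$phantom)[-1], as.character))
  write_json_artifact(lapply(unclass(cfg_serializable), unclass), cfg_file)
  emit(cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))

  manifest <- list(files = basename(files), seed = config$seed,
                   config_hash = cfg_hash, alert_runs = total_runs,
                   stages = stages_run)
  write_json_artifact(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}

#' Render a control chart
#'
#' Reproduces the standard chart anatomy: the moving-median curve, a solid
#' center line at the global median, dashed tolerance limits, green/red
#' shading under the in-control/out-of-control parts of the curve, and
#' optional gray background bands for calendar events (e.g. staff
#' rotations). A second chart (typically the other window size) can be
#' overlaid as a distinguishable line.
#'
#' @param chart A `control_chart`.
#' @param events Optional data frame with `from`, `to` dates (bands) or
#'   `name`/`date` (vertical lines).
#' @param file Optional output path (PNG/SVG by extension); when `NULL`
#'   the ggplot object is returned for on-screen use or inspection.
#' @param overlay Optional second `control_chart` drawn as an extra line.
#' @return The ggplot object, invisibly when written to file.
#' @export
render_chart <- function(chart, events = NULL, file = NULL, overlay = NULL) {
  stopifnot(inherits(chart, "control_chart"))
  df <- chart_frame(chart)
  df <- df[!is.na(df$mm), ]
  df$state <- ifelse(df$in_control, "in", "out")
  lim <- chart$limits
  p <- ggplot2::ggplot(df, ggplot2::aes(x = date, y = mm))
  if (!is.null(events) && all(c("from", "to") %in% names(events)))
    p <- p + ggplot2::geom_rect(
      data = events, inherit.aes = FALSE,
      ggplot2::aes(xmin = from, xmax = to, ymin = -Inf, ymax = Inf),
      fill = "grey85", alpha = 0.6)
  # shade towards the nearer limit so excursions read as red wedges
  if (any(df$state == "out"))
    p <- p + ggplot2::geom_ribbon(
      data = df[df$state == "out", , drop = FALSE],
      ggplot2::aes(ymin = pmin(mm, lim$upper), ymax = pmax(mm, lim$lower)),
      fill = "red", alpha = 0.3)
  p <- p +
    ggplot2::geom_ribbon(
      data = df[df$state == "in", , drop = FALSE],
      ggplot2::aes(ymin = pmin(mm, chart$center), ymax = pmax(mm, chart$center)),
      fill = "darkgreen", alpha = 0.15) +
    ggplot2::geom_hline(yintercept = chart$center, linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = c(lim$lower, lim$upper),
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_line(colour = "darkgreen")
  if (!is.null(overlay)) {
    df2 <- chart_frame(overlay)
    df2 <- df2[!is.na(df2$mm), ]
    p <- p + ggplot2::geom_line(data = df2, colour = "orange")
  }
  p <- p + ggplot2::labs(
    x = NULL, y = chart$parameter,
    title = sprintf("Moving median of %s (window %d)", chart$parameter,
                    chart$window)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 9, height = 4, dpi = 120)
    return(invisible(p))
  }
  p
}
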