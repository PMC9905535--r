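# Exam-table ingestion, inclusion filters and derived quantities.

#' Default column mapping for exam-report tables
#'
#' Maps each exam-record field to the column name expected in the input CSV.
#' Set an entry to `NA` to declare a field absent from the file.
#'
#' @return Named character vector with entries `exam_date`, `age`, `weight`,
#'   `height`, `sex`, `ef`, `edv`, `sv`, `lvm`.
#' @export
default_column_map <- function() {
  c(exam_date = "exam_date", age = "age", weight = "weight",
    height = "height", sex = "sex", ef = "ef", edv = "edv",
    sv = "sv", lvm = "lvm")
}

# Strict real-calendar date parsing. strptime() already rejects
# non-existent days, but we additionally require the round trip through
# format() to reproduce the field, so that any platform-side normalisation
# (e.g. day overflow) is rejected rather than silently shifted.
parse_one_format <- function(x, fmt) {
  d <- as.Date(x, format = fmt, optional = TRUE)
  ok <- !is.na(d) & format(d, fmt) == x
  d[!ok] <- NA
  d
}

parse_date_strict <- function(x, format = "%Y-%m-%d", fallback = NULL) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  d <- parse_one_format(x, format)
  bad <- !is.na(x) & is.na(d)
  if (!is.null(fallback) && any(bad))
    d[bad] <- parse_one_format(x[bad], fallback)
  d
}

#' Read an exam-report table from CSV
#'
#' Reads one row per examination from an RFC-4180 CSV file with a header
#' row, mapping columns to exam-record fields via `column_map`. Numeric
#' fields that fail to parse become missing values; dates that are not real
#' calendar dates (an existing day, month and year) are retained but flagged
#' invalid, never silently dropped.
#'
#' @param path Path to the CSV file.
#' @param column_map Named character vector as returned by
#'   [default_column_map()]; `NA` marks a field absent from the file.
#' @param date_format Primary date format (ISO-8601 by default).
#' @param fallback_format Optional second format tried for dates that fail
#'   the primary one.
#' @return A data frame of class `exam_table` with columns `exam_date`
#'   (`Date`, `NA` when invalid), `exam_date_raw`, `date_valid`, `age`,
#'   `weight`, `height`, `sex` (factor with levels `f`, `m`), `ef`, `edv`,
#'   `sv`, `lvm`, in file order.
#' @export
read_exam_table <- function(path, column_map = default_column_map(),
                            date_format = "%Y-%m-%d",
                            fallback_format = NULL) {
  if (!file.exists(path))
    stop("exam table not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  fields <- names(default_column_map())
  missing_fields <- setdiff(fields, names(column_map))
  if (length(missing_fields))
    stop("column_map lacks entries for: ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  mapped <- column_map[!is.na(column_map)]
  absent_cols <- setdiff(mapped, names(raw))
  if (length(absent_cols))
    stop("header lacks mapped column(s): ",
         paste(absent_cols, collapse = ", "), call. = FALSE)

  n <- nrow(raw)
  get_col <- function(field) {
    col <- column_map[[field]]
    if (is.na(col)) rep(NA_character_, n) else raw[[col]]
  }
  num <- function(field) suppressWarnings(as.numeric(get_col(field)))

  date_raw <- get_col("exam_date")
  dates <- parse_date_strict(date_raw, date_format, fallback_format)
  sex_raw <- tolower(trimws(get_col("sex")))
  sex <- rep(NA_character_, n)
  sex[sex_raw %in% c("f", "female", "w")] <- "f"
  sex[sex_raw %in% c("m", "male")] <- "m"

  out <- data.frame(
    exam_date = dates,
    exam_date_raw = as.character(date_raw),
    date_valid = !is.na(dates),
    age = num("age"), weight = num("weight"), height = num("height"),
    sex = factor(sex, levels = c("f", "m")),
    ef = num("ef"), edv = num("edv"), sv = num("sv"), lvm = num("lvm"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("exam_table", class(out))
  out
}

#' End-systolic volume from EDV and SV
#'
#' ESV is the difference of end-diastolic and stroke volume. Negative
#' results are physiologically implausible; they are flagged through the
#' `"implausible"` attribute but not clamped, so that the downstream
#' nonpositive-value inclusion filter removes them in one place.
#'
#' @param edv End-diastolic volume (ml).
#' @param sv Stroke volume (ml).
#' @return `edv - sv` (ml), `NA` where either input is missing, with a
#'   logical attribute `implausible` marking nonpositive results.
#' @export
derive_esv <- function(edv, sv) {
  esv <- edv - sv
  structure(esv, implausible = !is.na(esv) & esv <= 0)
}

#' Body surface area (Mosteller)
#'
#' @param height Height in cm.
#' @param weight Weight in kg.
#' @return BSA in m^2: `sqrt(height * weight / 3600)`. Nonpositive or
#'   missing inputs give `NA`, flagged via the `invalid_input` attribute.
#' @export
derive_bsa <- function(height, weight) {
  bad <- is.na(height) | is.na(weight) | height <= 0 | weight <= 0
  out <- ifelse(bad, NA_real_, sqrt(height * weight / 3600))
  structure(out, invalid_input = bad & !(is.na(height) & is.na(weight)))
}

#' Body mass index
#'
#' @param height Height in cm.
#' @param weight Weight in kg.
#' @return BMI in kg/m^2: `weight / (height / 100)^2`; `NA` with the
#'   `invalid_input` attribute set for nonpositive or missing inputs.
#' @export
derive_bmi <- function(height, weight) {
  bad <- is.na(height) | is.na(weight) | height <= 0 | weight <= 0
  out <- ifelse(bad, NA_real_, weight / (height / 100)^2)
  structure(out, invalid_input = bad & !(is.na(height) & is.na(weight)))
}

# Column of values for a parameter, computing derived quantities on the fly.
parameter_values <- function(records, parameter) {
  switch(parameter,
    esv = as.numeric(derive_esv(records$edv, records$sv)),
    bsa = as.numeric(derive_bsa(records$height, records$weight)),
    bmi = as.numeric(derive_bmi(records$height, records$weight)),
    records[[parameter]]
  )
}

#' Apply the per-parameter inclusion filters
#'
#' A data point is included when its value is present, its exam date is a
#' real calendar date, the value is strictly larger than zero, and strictly
#' smaller than `cap_factor` times the 99th percentile of the *uncleaned*
#' column (all nonmissing values, before any exclusion; date validity is an
#' independent filter and does not enter the cap). Each excluded entry
#' carries exactly one reason, assigned in the order `missing`,
#' `invalid_date`, `nonpositive`, `above_p99_cap`.
#'
#' @param records An `exam_table` (or any data frame with the same columns).
#' @param parameter One of [qc_parameters()].
#' @param percentile Percentile estimator for the cap: `"linear"`
#'   (interpolation between order statistics, [stats::quantile()] type 7,
#'   the default) or `"nearest"` (nearest-rank, type 1). The choice moves
#'   the cap only at the margin.
#' @param cap_factor Multiplier applied to the 99th percentile (default 1.5).
#' @return A list with components
#'   \describe{
#'     \item{series}{a `parameter_series` data frame with columns
#'       `exam_date`, `value`, `included`, `reason`, sorted by date (stable
#'       for ties; entries with invalid dates are kept, flagged, at the
#'       end);}
#'     \item{report}{a `cleaning_report` list with `parameter`, `n_input`,
#'       `n_included`, `n_excluded_by_reason`, `cap_value`.}
#'   }
#' @export
clean_parameter <- function(records, parameter,
                            percentile = c("linear", "nearest"),
                            cap_factor = 1.5) {
  parameter <- match.arg(parameter, qc_parameters())
  percentile <- match.arg(percentile)
  values <- parameter_values(records, parameter)
  if (all(is.na(values)))
    stop("all values missing for parameter '", parameter, "'", call. = FALSE)

  qtype <- if (percentile == "linear") 7L else 1L
  p99 <- stats::quantile(values, 0.99, na.rm = TRUE, names = FALSE,
                         type = qtype)
  cap <- cap_factor * p99

  date_valid <- if ("date_valid" %in% names(records)) records$date_valid
                else !is.na(records$exam_date)
  reason <- rep(NA_character_, length(values))
  reason[is.na(values)] <- "missing"
  reason[is.na(reason) & !date_valid] <- "invalid_date"
  reason[is.na(reason) & values <= 0] <- "nonpositive"
  reason[is.na(reason) & values >= cap] <- "above_p99_cap"
  included <- is.na(reason)

  series <- data.frame(exam_date = records$exam_date, value = values,
                       included = included, reason = reason,
                       stringsAsFactors = FALSE)
  # stable date sort; invalid dates (NA) collected at the end
  ord <- order(series$exam_date, na.last = TRUE)
  series <- series[ord, , drop = FALSE]
  rownames(series) <- NULL
  attr(series, "parameter") <- parameter
  class(series) <- c("parameter_series", class(series))

  counts <- table(reason)
  report <- structure(list(
    parameter = parameter,
    n_input = length(values),
    n_included = sum(included),
    n_excluded_by_reason = as.list(counts),
    cap_value = cap,
    percentile = percentile,
    cap_factor = cap_factor
  ), class = "cleaning_report")
  stopifnot(report$n_input ==
              report$n_included + sum(unlist(report$n_excluded_by_reason)))
  list(series = series, report = report)
}

#' Intersection inclusion across several parameters
#'
#' The per-parameter filter is the primary procedure; for cohort-style
#' summaries it is sometimes useful to keep only examinations that pass the
#' filter for *every* listed parameter.
#'
#' @param records An `exam_table`.
#' @param parameters Parameters whose filters must all pass.
#' @inheritParams clean_parameter
#' @return Logical vector, `TRUE` for rows included for all parameters.
#' @export
included_for_all <- function(records, parameters = c("ef", "edv", "sv", "lvm"),
                             percentile = c("linear", "nearest"),
                             cap_factor = 1.5) {
  percentile <- match.arg(percentile)
  masks <- lapply(parameters, function(p) {
    cl <- clean_parameter(records, p, percentile, cap_factor)
    # map back to input order: reconstruct from unsorted reasons
    values <- parameter_values(records, p)
    date_valid <- if ("date_valid" %in% names(records)) records$date_valid
                  else !is.na(records$exam_date)
    !is.na(values) & date_valid & values > 0 & values < cl$report$cap_value
  })
  Reduce(`&`, masks)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("Cleaning report for '%s': %d of %d included (cap %.4g)\n",
              x$parameter, x$n_included, x$n_input, x$cap_value))
  for (r in names(x$n_excluded_by_reason))
    cat(sprintf("  excluded %-14s %d\n", r, x$n_excluded_by_reason[[r]]))
  invisible(x)
}

#' Write a cleaned series to CSV
#'
#' @param series A `parameter_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
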