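# Independent oracles and fixture builders shared across the suite.

# Brute-force trailing moving median: per-window sort and explicit order
# statistic picks. Deliberately independent of the package's sliding-buffer
# implementation (and of stats::median).
oracle_mm <- function(values, w) {
  n <- length(values)
  out <- rep(NA_real_, n)
  for (i in w:n) {
    s <- sort(values[(i - w + 1):i])
    out[i] <- if (w %% 2 == 1) s[(w + 1) / 2] else (s[w / 2] + s[w / 2 + 1]) / 2
  }
  out
}

# First-alert delay of a deterministic step series, by direct enumeration:
# values `a` before onset, `a + magnitude` from onset on; alert when the
# window median is strictly outside [lower, upper]. Returns delay in
# samples (first alerting index minus onset) or NA.
oracle_step_delay <- function(a, magnitude, onset, n, w, lower, upper) {
  v <- c(rep(a, onset - 1), rep(a + magnitude, n - onset + 1))
  med <- oracle_mm(v, w)
  for (i in max(w, onset):n) {
    if (!is.na(med[i]) && (med[i] > upper || med[i] < lower))
      return(i - onset)
  }
  NA_integer_
}

write_exam_csv <- function(path, rows) {
  header <- "exam_date,age,weight,height,sex,ef,edv,sv,lvm"
  writeLines(c(header, rows), path)
  path
}

# A plain cleaned series wrapper for chart construction in tests.
as_series <- function(values, dates = as.Date("2015-01-01") + seq_along(values) - 1,
                      parameter = "sv") {
  s <- data.frame(exam_date = dates, value = values, included = TRUE,
                  reason = NA_character_)
  attr(s, "parameter") <- parameter
  class(s) <- c("parameter_series", class(s))
  s
}

small_phantom <- function(n = 2000, seed = 11) {
  default_phantom_config(n_samples = n, seed = seed)
}
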