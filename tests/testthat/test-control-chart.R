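test_that("moving median matches hand medians and rejects bad windows", {
  expect_equal(moving_median(c(1, 2, 3, 4, 100), 3), c(NA, NA, 2, 3, 4))
  expect_equal(moving_median(rep(7.5, 20), 6), c(rep(NA, 5), rep(7.5, 15)))
  expect_error(moving_median(1:5, 6), "exceeds")
  expect_error(moving_median(1:5, 0), "positive")
  expect_error(moving_median(c(1, NA, 3), 2), "missing")
})

test_that("moving median equals the sort-and-pick oracle on random series", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(30:200, 1)
    w <- sample(1:20, 1)
    v <- rnorm(n, 80, 25)
    expect_identical(moving_median(v, w), oracle_mm(v, w))
  }
})

test_that("moving median is location-equivariant and multiset-determined", {
  set.seed(102)
  v <- rnorm(300, 86, 10)
  # shifts keeping the central values inside one binade, so v + c is exact
  # where the median is taken; bit-for-bit equality is then guaranteed
  for (c0 in c(5, -12, 20)) {
    expect_identical(moving_median(v + c0, 7), moving_median(v, 7) + c0)
    expect_identical(moving_median(v + c0, 10), moving_median(v, 10) + c0)
  }
  # the value at index i depends only on the window's multiset
  w <- 15
  v2 <- v
  v2[51:65] <- v[sample(51:65)]
  expect_equal(moving_median(v2, w)[65], moving_median(v, w)[65])
})

test_that("charts populate center, limits and the alert mask correctly", {
  s <- as_series(rep(c(70, 90), 50))
  lim <- tolerance_interval("sv", 60, 100)
  ch <- build_chart(s, 10, lim)
  expect_s3_class(ch, "control_chart")
  expect_equal(sum(is.na(ch$mm)), 9)
  expect_equal(ch$center, 80)
  expect_false(any(ch$alert, na.rm = TRUE))
  expect_equal(nrow(detect_alerts(ch)), 0)

  # constant series above the upper limit: every defined entry one run
  ch2 <- build_chart(as_series(rep(120, 40)), 5, lim)
  expect_true(all(ch2$alert[!is.na(ch2$alert)]))
  runs <- detect_alerts(ch2)
  expect_equal(nrow(runs), 1)
  expect_equal(c(runs$start, runs$end, runs$direction), c("5", "40", "above"))

  # a value exactly on the limit is in control under the strict rule
  ch3 <- build_chart(as_series(rep(100, 20)), 4, lim)
  expect_false(any(ch3$alert, na.rm = TRUE))
  ch4 <- build_chart(as_series(rep(100, 20)), 4, lim, strict = FALSE)
  expect_true(all(ch4$alert, na.rm = TRUE))

  expect_error(build_chart(as_series(rnorm(5, 80)), 10, lim), "sv.*10")
})

test_that("alert runs partition the mask and split on direction changes", {
  lim <- tolerance_interval("x", -5, 5)
  # window 1: the moving median is the series itself
  ch <- build_chart(as_series(c(1, 1, 9, 9, 1, 9)), 1, lim)
  runs <- detect_alerts(ch)
  expect_equal(runs$start, c(3, 6))
  expect_equal(runs$end, c(4, 6))
  expect_equal(sum(runs$length), sum(ch$alert, na.rm = TRUE))

  # crossing from above-upper straight to below-lower yields two runs
  ch2 <- build_chart(as_series(c(0, 9, -9, 0)), 1, lim)
  runs2 <- detect_alerts(ch2)
  expect_equal(nrow(runs2), 2)
  expect_equal(runs2$direction, c("above", "below"))
  expect_equal(runs2$peak, c(4, 4))
})

test_that("alert percentages aggregate per year and average per period", {
  lim <- tolerance_interval("x", -5, 5)
  dates <- c(as.Date("2011-03-01") + seq_len(200),
             as.Date("2012-03-01") + seq_len(100))
  v <- c(rep(0, 150), rep(9, 50),          # 2011: 50 of 200 entries alert
         rep(9, 30), rep(0, 70))           # 2012: 30 of 100 entries alert
  ch <- build_chart(as_series(v, dates = dates), 1, lim)
  summ <- aggregate_alerts(ch, periods = list(
    all = c(as.Date("2011-01-01"), as.Date("2012-12-31"))))
  expect_equal(unname(summ$per_year["2011"]), 25)
  expect_equal(unname(summ$per_year["2012"]), 30)
  expect_equal(unname(summ$per_period["all"]), 27.5)
  expect_true(all(summ$per_year >= 0 & summ$per_year <= 100))

  # no alerts anywhere: zeros in every year and period
  ch0 <- build_chart(as_series(rep(0, 300), dates = dates), 1, lim)
  s0 <- aggregate_alerts(ch0, periods = list(
    all = c(as.Date("2011-01-01"), as.Date("2012-12-31"))))
  expect_true(all(s0$per_year == 0) && all(s0$per_period == 0))

  # a period with no represented years is dropped with a warning
  expect_warning(
    aggregate_alerts(ch, periods = list(
      early = c(as.Date("2011-01-01"), as.Date("2012-12-31")),
      empty = c(as.Date("1990-01-01"), as.Date("1995-12-31")))),
    "empty")
})

test_that("percentages recompute from the mask and warm-up entries are excluded", {
  set.seed(103)
  s <- as_series(rnorm(400, 85, 20))
  ch <- build_chart(s, 50, tolerance_interval("sv", 80, 90))
  summ <- suppressWarnings(aggregate_alerts(ch))
  def <- !is.na(ch$alert)
  expect_equal(sum(def), 351)
  by_year <- tapply(ch$alert[def], format(ch$dates[def], "%Y"), mean)
  expect_equal(unname(summ$per_year), unname(100 * by_year))
})

test_that("widening the tolerance interval never increases alerts", {
  set.seed(104)
  for (rep in 1:25) {
    v <- rnorm(150, 85, 25)
    s <- as_series(v)
    lo <- runif(1, 60, 84); hi <- runif(1, 86, 110)
    w <- sample(2:30, 1)
    n1 <- sum(build_chart(s, w, tolerance_interval("sv", lo, hi))$alert,
              na.rm = TRUE)
    n2 <- sum(build_chart(s, w, tolerance_interval("sv", lo - 2, hi + 3))$alert,
              na.rm = TRUE)
    expect_lte(n2, n1)
  }
})
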