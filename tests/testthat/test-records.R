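test_that("exam tables parse row-wise with strict calendar validation", {
  f <- write_exam_csv(tempfile(fileext = ".csv"), c(
    "2010-01-05,60,80,180,m,62,121,74,99",
    "2010-02-30,55,70,165,f,65,110,70,90",
    "2010-03-01,50,,170,f,,130,80,95"))
  tab <- read_exam_table(f)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$exam_date[1], as.Date("2010-01-05"))
  expect_equal(tab$ef[1], 62)
  expect_equal(tab$sv[1], 74)
  expect_equal(as.character(tab$sex), c("m", "f", "f"))
  # February 30th is not a real calendar date: flagged, not dropped
  expect_false(tab$date_valid[2])
  expect_true(is.na(tab$exam_date[2]))
  expect_equal(tab$exam_date_raw[2], "2010-02-30")
  # empty cells become missing, the rest of the row is intact
  expect_true(is.na(tab$ef[3]) && is.na(tab$weight[3]))
  expect_equal(tab$edv[3], 130)
})

test_that("unparseable numerics become missing and errors name the problem", {
  f <- write_exam_csv(tempfile(fileext = ".csv"),
                      "2010-01-05,sixty,80,180,m,62,121,74,99")
  expect_true(is.na(read_exam_table(f)$age))
  expect_error(read_exam_table(tempfile()), "not found")
  cm <- default_column_map()
  cm["ef"] <- "ejection_fraction"
  expect_error(read_exam_table(f, cm), "ejection_fraction")
})

test_that("a fallback date format is honoured", {
  f <- write_exam_csv(tempfile(fileext = ".csv"),
                      "05.01.2010,60,80,180,m,62,121,74,99")
  tab <- read_exam_table(f, fallback_format = "%d.%m.%Y")
  expect_equal(tab$exam_date, as.Date("2010-01-05"))
})

test_that("inclusion rules are strict at zero and at the percentile cap", {
  tab <- data.frame(exam_date = as.Date("2011-01-01") + 0:3,
                    date_valid = TRUE,
                    sv = c(0, 50, 60, 70))
  cl <- clean_parameter(tab, "sv")
  expect_equal(sum(cl$series$included), 3)
  expect_equal(cl$report$n_excluded_by_reason$nonpositive, 1)

  # cap computed on the full uncleaned column, outlier excluded iff >= cap
  tab2 <- data.frame(exam_date = as.Date("2011-01-01") + 0:100,
                     date_valid = TRUE,
                     sv = c(rep(100, 100), 10000))
  cl2 <- clean_parameter(tab2, "sv")
  p99 <- sort(tab2$sv)[ (101 - 1) * 0.99 + 1 ]  # h lands on an order statistic
  expect_equal(cl2$report$cap_value, 1.5 * p99)
  expect_equal(10000 >= cl2$report$cap_value, !cl2$series$included[101])
  expect_equal(cl2$report$n_excluded_by_reason$above_p99_cap, 1)

  # brute-force type-7 percentile for a tiny column
  tab3 <- data.frame(exam_date = as.Date("2011-01-01") + 0:2,
                     date_valid = TRUE, sv = c(10, 20, 30))
  cl3 <- clean_parameter(tab3, "sv")
  h <- (3 - 1) * 0.99 + 1
  p99_by_hand <- 20 + (h - 2) * (30 - 20)
  expect_equal(cl3$report$cap_value, 1.5 * p99_by_hand)
  expect_equal(sum(cl3$series$included), 3)

  # nearest-rank alternative: ceiling(n p)-th order statistic
  cl4 <- clean_parameter(tab3, "sv", percentile = "nearest")
  expect_equal(cl4$report$cap_value, 1.5 * sort(tab3$sv)[ceiling(3 * 0.99)])
})

test_that("every excluded entry carries exactly one reason and counts add up", {
  tab <- data.frame(
    exam_date = as.Date(c("2011-01-01", NA, "2011-01-03", "2011-01-04", NA)),
    date_valid = c(TRUE, FALSE, TRUE, TRUE, FALSE),
    sv = c(70, 75, NA, -5, NA))
  cl <- clean_parameter(tab, "sv")
  r <- cl$report
  expect_equal(r$n_input, 5)
  expect_equal(r$n_included + sum(unlist(r$n_excluded_by_reason)), 5)
  excl <- cl$series[!cl$series$included, ]
  expect_true(all(!is.na(excl$reason)))
  # a missing value with an invalid date is reported as missing
  expect_equal(sort(unlist(r$n_excluded_by_reason[c("missing", "invalid_date",
                                                    "nonpositive")])),
               sort(c(missing = 2L, invalid_date = 1L, nonpositive = 1L)))
})

test_that("cleaning is idempotent and order-insensitive", {
  set.seed(42)
  tab <- data.frame(exam_date = as.Date("2012-01-01") + 0:199,
                    date_valid = TRUE,
                    sv = rnorm(200, 85, 20))
  cl1 <- clean_parameter(tab, "sv")
  inc <- cl1$series[cl1$series$included, c("exam_date", "value")]
  # re-clean the included values: the cap can only tighten, and with no
  # near-cap values nothing new is excluded
  tab2 <- data.frame(exam_date = inc$exam_date, date_valid = TRUE,
                     sv = inc$value)
  cl2 <- clean_parameter(tab2, "sv")
  expect_equal(sum(!cl2$series$included), 0)
  expect_lte(cl2$report$cap_value, cl1$report$cap_value)

  # permuting input rows never changes the included multiset
  perm <- sample(nrow(tab))
  cl3 <- clean_parameter(tab[perm, ], "sv")
  expect_equal(sort(cl3$series$value[cl3$series$included]),
               sort(cl1$series$value[cl1$series$included]))
})

test_that("derived quantities follow their defining formulas", {
  expect_equal(as.numeric(derive_esv(121, 74)), 47)
  expect_equal(as.numeric(derive_esv(88, 88)), 0)
  esv <- derive_esv(100, 120)
  expect_equal(as.numeric(esv), -20)
  expect_true(attr(esv, "implausible"))
  expect_true(is.na(derive_esv(NA, 74)))
  # difference identity holds exactly
  edv <- c(121, 150.3, 99.7); sv <- c(74, 80.1, 45.2)
  expect_identical(as.numeric(derive_esv(edv, sv)) + sv, edv)

  expect_equal(as.numeric(derive_bsa(180, 80)), 2.0)
  expect_equal(as.numeric(derive_bsa(100, 36)), 1.0)
  expect_equal(as.numeric(derive_bsa(164, 70)), sqrt(164 * 70 / 3600))
  bad <- derive_bsa(-1, 70)
  expect_true(is.na(bad) && attr(bad, "invalid_input"))

  expect_equal(as.numeric(derive_bmi(200, 100)), 25)
  expect_equal(as.numeric(derive_bmi(100, 50)), 50)
  expect_equal(as.numeric(derive_bmi(177, 85)), 85 / 1.77^2)
  expect_true(is.na(derive_bmi(170, 0)))
})

test_that("derived parameters clean through the same filter", {
  tab <- data.frame(exam_date = as.Date("2013-05-01") + 0:3,
                    date_valid = TRUE,
                    edv = c(121, 100, 150, 140),
                    sv = c(74, 120, 80, 75))
  cl <- clean_parameter(tab, "esv")
  # the negative derived ESV (100 - 120) falls to the nonpositive rule
  expect_equal(cl$report$n_excluded_by_reason$nonpositive, 1)
  expect_equal(sum(cl$series$included), 3)
  expect_error(clean_parameter(data.frame(exam_date = Sys.Date(),
                                          date_valid = TRUE, sv = NA_real_),
                               "sv"), "sv")
})

test_that("intersection mode keeps only rows passing every filter", {
  tab <- data.frame(exam_date = as.Date("2014-01-01") + 0:4,
                    date_valid = TRUE,
                    ef = c(60, 0, 55, 62, 58),
                    sv = c(70, 80, -2, 75, 72),
                    edv = c(120, 130, 125, 140, 135),
                    lvm = c(100, 95, 90, 105, 98))
  keep <- included_for_all(tab)
  expect_equal(keep, c(TRUE, FALSE, FALSE, TRUE, TRUE))
})
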