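test_that("percentile dates interpolate linearly between observations", {
  cv <- data.frame(julian = c(260, 262), percent = c(40, 60))
  expect_equal(percentile_dates(cv, 50), 261)
  # exact hit returns the plotted date
  expect_equal(percentile_dates(cv, 60), 262)
  # percentile met at the first point returns the first date
  expect_equal(percentile_dates(cv, 40), 260)
  expect_equal(percentile_dates(cv, 30), 260)
  # above the maximum: explicit not-reached error
  top <- data.frame(julian = c(250, 260), percent = c(50, 95))
  expect_error(percentile_dates(top, 99), "not reached")
})

test_that("percentile dates are monotone in the percentile", {
  set.seed(8)
  f <- sort(runif(20))
  cv <- data.frame(julian = 200 + 1:20, fraction = f / max(f))
  p <- seq(5, 100, by = 5)
  expect_true(all(diff(percentile_dates(cv, p)) >= 0))
})

test_that("curve coercion accepts fractions, percents and raw counts", {
  a <- as_emergence_curve(data.frame(julian = 1:3,
                                     fraction = c(0.2, 0.5, 1)))
  b <- as_emergence_curve(data.frame(julian = 1:3,
                                     percent = c(20, 50, 100)))
  cc <- as_emergence_curve(data.frame(julian = 1:3, count = c(4, 10, 20)))
  expect_equal(a$fraction, b$fraction)
  expect_equal(a$fraction, cc$fraction)
  expect_error(as_emergence_curve(data.frame(julian = c(2, 1),
                                             fraction = c(0.1, 1))),
               "increasing")
  expect_error(as_emergence_curve(data.frame(julian = 1:2,
                                             fraction = c(0.9, 0.4))),
               "non-decreasing")
})

test_that("the 1986/1987 field-comparison statistics are recomputed", {
  t86 <- load_fixture("emergence_1986")
  cmp86 <- compare_emergence(
    data.frame(percent = t86$percent, julian = t86$observed),
    data.frame(percent = t86$percent, julian = t86$predicted),
    percentiles = t86$percent)
  expect_equal(cmp86$table$difference, c(11, 8, 6.5, 7, 9, 7, 5))
  expect_equal(cmp86$mean_difference, 7.642857, tolerance = 1e-6)
  expect_equal(cmp86$se, 0.7296, tolerance = 1e-4)
  expect_gt(cmp86$t_statistic, 0)  # mean discrepancy above the 5-day null
  expect_true(cmp86$significant)

  t87 <- load_fixture("emergence_1987")
  cmp87 <- compare_emergence(
    data.frame(percent = t87$percent, julian = t87$observed),
    data.frame(percent = t87$percent, julian = t87$predicted),
    percentiles = t87$percent)
  expect_equal(cmp87$mean_difference, 4.785714, tolerance = 1e-6)
  expect_equal(abs(cmp87$t_statistic), 0.1891, tolerance = 1e-3)
  expect_false(cmp87$significant)

  # statistics agree with stats::t.test on the same absolute differences
  tt <- t.test(cmp86$table$difference, mu = 5)
  expect_equal(cmp86$t_statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(cmp86$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("a uniform 5-day offset gives t = 0 under the 5-day null", {
  obs <- data.frame(julian = c(250, 260, 270),
                    percent = c(10, 50, 100))
  pred <- transform(obs, julian = julian + 5)
  cmp <- compare_emergence(obs, pred, percentiles = c(10, 50, 100))
  expect_equal(cmp$mean_difference, 5)
  expect_equal(cmp$t_statistic, 0)

  expect_equal(cmp$p_value, 1)

  single <- compare_emergence(obs, pred, percentiles = 50)
  expect_equal(single$mean_difference, 5)
  expect_true(is.na(single$t_statistic))
})
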