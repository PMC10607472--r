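test_that("common base temperature averages and rounds stage thresholds", {
  expect_equal(common_base_temperature(c(3.1, 3.8, 4.3, 4.0, 4.4)), 3.9)
  expect_equal(common_base_temperature(5), 5)
  expect_equal(common_base_temperature(c(0, 10)), 5)
  expect_error(common_base_temperature(numeric(0)))
})

test_that("thermal constant is the day-degree product above the base", {
  expect_equal(thermal_constant(1, 23, 3.9), 19.1)
  expect_equal(thermal_constant(8.6, 25, 3.9), 181.46)
  expect_error(thermal_constant(2, 3.9, 3.9), "exceed")
  expect_error(thermal_constant(0, 23, 3.9), "positive")
})

test_that("stage constants sum to the generation totals", {
  sc <- stage_constants()
  expect_equal(sc$t_cb, 3.9)
  expect_equal(sum(sc$dd), 650.9)
  expect_equal(sc$egg_to_egg, 650.9)
  expect_equal(sc$adult_to_pupa, 433.9)
  expect_equal(sc$backtrack, 414.8)
})

test_that("degree-day accumulation matches a brute-force daily sum", {
  w <- constant_weather(23.9, 40)
  track <- accumulate_dd(w, t_cb = 3.9)
  expect_equal(track$increment, rep(20, 40))
  expect_equal(track$cumulative, cumsum(rep(20, 40)))

  # all days below the base accumulate nothing
  cold <- constant_weather(2.0, 30)
  expect_equal(accumulate_dd(cold, t_cb = 3.9)$cumulative, rep(0, 30))

  # mixed series equals the sum of positive excesses, day by day
  set.seed(5)
  n <- 60
  tmin <- runif(n, -2, 12)
  mixed <- weather_series(as.Date("2022-03-01") + 0:(n - 1), tmin, tmin + 8)
  got <- accumulate_dd(mixed, t_cb = 3.9)$cumulative
  brute <- cumsum(pmax(0, mixed$tmean_soil - 3.9))
  expect_equal(got, brute)
})

test_that("forward tracking finds the first crossing date", {
  w <- constant_weather(23.9, 60)           # 20 DD/day
  track <- accumulate_dd(w, t_cb = 3.9)
  # 650.9 DD at 20 DD/day completes on the 33rd day of accumulation
  expect_equal(date_at_dd(track, 650.9), w$date[1] + 32)
  expect_equal(date_at_dd(track, 0), w$date[1])
  cold <- constant_weather(2.0, 30)
  expect_warning(res <- date_at_dd(accumulate_dd(cold), 100),
                 "not completed")
  expect_true(is.na(res))
})

test_that("backward tracking inverts forward tracking within one day", {
  w <- constant_weather(23.9, 120)          # 20 DD/day
  end <- w$date[100]
  expect_equal(backtrack_date(w, end, 400), w$date[80])
  expect_equal(backtrack_date(w, end, 0), end)

  # round trip on random series: forward from the backtracked date reaches
  # the target no later than the end date
  set.seed(21)
  for (k in 1:5) {
    tmin <- runif(150, 5, 20)
    ws <- weather_series(as.Date("2022-06-01") + 0:149, tmin, tmin + 8)
    end <- ws$date[140]
    target <- runif(1, 100, 1200)
    d0 <- backtrack_date(ws, end, target)
    if (is.na(d0)) next
    reach <- date_at_dd(accumulate_dd(ws, start = d0), target)
    expect_lte(as.numeric(reach - end), 1)
  }

  cold <- constant_weather(2.0, 30)
  expect_warning(res <- backtrack_date(cold, cold$date[30], 50),
                 "cannot be accumulated")
  expect_true(is.na(res))
})
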