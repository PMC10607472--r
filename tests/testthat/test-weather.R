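test_that("daily mean and soil conversion follow their definitions", {
  expect_equal(daily_mean(10, 20), 15)
  expect_equal(daily_mean(-5, 5), 0)
  expect_equal(daily_mean(7.3, 7.3), 7.3)
  expect_error(daily_mean(21, 20), "tmin")

  expect_equal(air_to_soil(20), 20.9)
  expect_equal(air_to_soil(25), 25.6)
  # the 23.3 degC boundary takes the +0.6 branch
  expect_equal(air_to_soil(23.3), 23.9)
  expect_equal(air_to_soil(23.3 - 1e-9), 23.3 - 1e-9 + 0.9)
  # offset is exactly 0.6 or 0.9 for every day
  x <- seq(-10, 35, by = 0.1)
  expect_true(all(round(air_to_soil(x) - x, 10) %in% c(0.6, 0.9)))
})

test_that("trailing moving average shrinks at the start and is bounded", {
  expect_equal(moving_average(c(10, 16, 22), 3), c(10, 13, 16))
  expect_equal(moving_average(rep(4.2, 10), 3), rep(4.2, 10))
  x <- sin(1:50)
  expect_equal(moving_average(x, 1), x)
  ma <- moving_average(x, 5)
  for (i in seq_along(x)) {
    win <- x[max(1, i - 4):i]
    expect_gte(ma[i], min(win) - 1e-12)
    expect_lte(ma[i], max(win) + 1e-12)
  }
})

test_that("weather series validates ordering, gaps and tmin <= tmax", {
  d <- as.Date("2022-08-01") + 0:4
  w <- weather_series(d, rep(15, 5), rep(25, 5))
  expect_s3_class(w, "weather_series")
  expect_equal(w$tmean_air, rep(20, 5))
  expect_equal(w$tmean_soil, rep(20.9, 5))
  expect_equal(w$julian, rep(as.POSIXlt(d[1])$yday + 1, 5) + 0:4)

  expect_error(weather_series(d[c(1, 2, 4, 5)], rep(15, 4), rep(25, 4)),
               "gap")
  expect_error(weather_series(d, rep(15, 5), c(25, 25, 10, 25, 25)), "tmin")
})

test_that("weather CSV round-trips and rejects gaps", {
  w <- synthetic_weather("cool-temperate", year = 2021, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_weather(w, path)
  w2 <- read_weather(path)
  expect_equal(w2$tmean_soil, w$tmean_soil, tolerance = 1e-9)
  expect_equal(w2$date, w$date)

  gap <- read.csv(path)[-5, ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(gap, path2, row.names = FALSE)
  expect_error(read_weather(path2), "gap")
})

test_that("synthetic weather is reproducible and honours its parameters", {
  a <- synthetic_weather("jinju-like", year = 2022, seed = 9)
  b <- synthetic_weather("jinju-like", year = 2022, seed = 9)
  expect_identical(a, b)
  c2 <- synthetic_weather("jinju-like", year = 2022, seed = 10)
  expect_false(identical(a$tmean_air, c2$tmean_air))

  # zero amplitude and noise give a constant series at the annual mean
  flat <- synthetic_weather(annual_mean = 12, amplitude = 0, noise_sd = 0,
                            diurnal_range = 4, year = 2022)
  expect_true(all(flat$tmean_air == 12))
  expect_true(all(flat$tmax_air - flat$tmin_air == 4))

  expect_error(synthetic_weather("mars-like"), "unknown weather profile")
})

test_that("regional presets produce their summer exceedance signatures", {
  limit <- 22.1
  for (seed in 1:3) {
    jeju <- synthetic_weather("jeju-like", year = 2022, seed = seed)
    jinju <- synthetic_weather("jinju-like", year = 2022, seed = seed)
    cool <- synthetic_weather("cool-temperate", year = 2022, seed = seed)

    runlen <- function(w) {
      r <- rle(w$tmean_soil > limit)
      max(c(0, r$lengths[r$values]))
    }
    # warm maritime profile: at least 60 consecutive hot soil days
    expect_gte(runlen(jeju), 60)
    # hot continental summer, but a shorter exceedance than the maritime one
    expect_gte(runlen(jinju), 30)
    expect_lt(runlen(jinju), runlen(jeju))
    # cool-temperate: July-August soil means rarely exceed the limit
    ja <- cool[format(cool$date, "%m") %in% c("07", "08"), ]
    expect_lt(mean(ja$tmean_soil > limit), 0.10)
  }
})
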