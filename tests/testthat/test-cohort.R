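test_that("a single day step transfers the CDF increment of the SDT age", {
  st <- sim_state(sim_config(n0 = 1000))
  st <- step_day(st, t3d_soil = 16, tmean_soil = 16)
  # direct-evaluation oracle: x advances by the 16 degC rate, and the
  # transferred fraction is the Weibull CDF at that age
  r16 <- exp(0.16978 * 16) -
    exp(0.16978 * 22.13802 - (22.13802 - 16) / 5.67016)
  expected <- 1 - exp(-(r16 / 1.1546)^1.71717)
  expect_equal(st$today$transferred, 1000 * expected, tolerance = 1e-6)
  expect_equal(expected, 0.2767, tolerance = 1e-3)
  expect_equal(st$aest$x, r16, tolerance = 1e-9)
  # the new pupal cohort starts at age 0 and does not advance today
  expect_equal(st$pupal$px, 0)
  expect_equal(st$today$adults_new, 0)
  # bookkeeping identity
  expect_equal(st$today$aestivating + st$today$pupae + st$today$adults_cum,
               1000)
})

test_that("diapause termination is arrested at and above the thermal maximum", {
  st <- sim_state(sim_config(n0 = 1000))
  for (t3 in c(22.138021, 25, 30)) {
    st <- step_day(st, t3d_soil = t3, tmean_soil = t3)
    expect_equal(st$aest$x, 0)
    expect_equal(st$today$transferred, 0)
  }
  expect_equal(st$today$aestivating, 1000)
})

test_that("hot weather throughout yields zero emergence", {
  w <- constant_weather(25, 200)
  sim <- run_simulation(w, sim_config(start = w$date[1]))
  expect_equal(sim$total_emerged, 0)
  expect_equal(max(sim$daily$adults_cum), 0)
  expect_s3_class(emergence_curve(sim), "emergence_curve")
  expect_equal(nrow(emergence_curve(sim)), 0L)
})

test_that("constant 16 degC reproduces the independent convolution oracle", {
  w <- constant_weather(16, 80)
  sim <- run_simulation(w, sim_config(start = w$date[1]))
  # everyone emerges within 60 days
  i60 <- which(sim$daily$date == w$date[1] + 59)
  expect_equal(sim$daily$adults_cum[i60], 1000, tolerance = 1e-6)

  r_s <- lactin_rate(16, SDT_RATE)
  r_p <- lactin_rate(16, PUP_RATE)
  oracle <- convolution_oracle(1000, r_s, 1.15460, 1.71717,
                               r_p, 1.121146325, 3.155020615, horizon = 80)
  got <- oracle_percentile_days(sim$daily$adults_new, c(10, 50, 90))
  want <- oracle_percentile_days(oracle, c(10, 50, 90))
  expect_true(all(abs(got - want) <= 1))
  # median emergence day ~ SDT median (~2 d) + pupal time at 16 degC (~21 d)
  expect_gt(want[2], 18)
  expect_lt(want[2], 28)
})

test_that("mass is conserved every day across weather profiles", {
  for (profile in c("jinju-like", "jeju-like", "cool-temperate")) {
    w <- synthetic_weather(profile, year = 2022, seed = 4)
    sim <- run_simulation(w, sim_config())
    d <- sim$daily
    expect_lt(max(abs(d$aestivating + d$pupae + d$adults_cum - 1000)), 1e-8)
    expect_true(all(diff(d$adults_cum) >= -1e-12))
    expect_true(all(d$adults_new >= 0))
    expect_lte(max(d$adults_cum), 1000 + 1e-8)
  }
})

test_that("daily outputs scale linearly with the initial cohort size", {
  w <- synthetic_weather("jinju-like", year = 2022, seed = 4)
  s1 <- run_simulation(w, sim_config(n0 = 1000))
  s2 <- run_simulation(w, sim_config(n0 = 10000))
  expect_equal(s2$daily$adults_new, 10 * s1$daily$adults_new,
               tolerance = 1e-10)
  # and the scaled emergence curves are identical
  expect_equal(emergence_curve(s2)$fraction, emergence_curve(s1)$fraction,
               tolerance = 1e-10)
})

test_that("under a hot-summer profile emergence follows the arrest period", {
  w <- synthetic_weather("jinju-like", year = 2022, seed = 42)
  sim <- run_simulation(w, sim_config())
  d <- sim$daily
  limit <- lactin_upper_limit(sdt_defaults()$rate)
  last_hot <- max(d$date[d$t3d_soil > limit])
  # almost all emergence happens after diapause termination resumes
  cum_at_arrest <- max(0, d$adults_cum[d$date == last_hot])
  expect_lt(cum_at_arrest, 0.05 * sim$total_emerged)
  expect_gt(sim$total_emerged, 900)
})

test_that("emergence curve is a valid scaled CDF", {
  w <- synthetic_weather("jinju-like", year = 2022, seed = 4)
  sim <- run_simulation(w, sim_config())
  cv <- emergence_curve(sim)
  expect_true(all(diff(cv$fraction) >= -1e-12))
  expect_equal(max(cv$fraction), 1)
  expect_true(all(diff(cv$julian) == 1))
})

test_that("the Monte Carlo realization converges to the cohort expectation", {
  w <- synthetic_weather("jinju-like", year = 2022, seed = 4)
  sim <- run_simulation(w, sim_config())
  mc <- simulate(sim, nsim = 2, seed = 99, n = 20000)
  expect_identical(simulate(sim, nsim = 2, seed = 99, n = 20000), mc)
  pct <- c(25, 50, 75)
  det <- oracle_percentile_days(sim$daily$adults_new, pct)
  for (k in 1:2) {
    counts <- mc[[paste0("adults_new.", k)]]
    expect_true(all(abs(oracle_percentile_days(counts, pct) - det) <= 1.5))
  }
})

test_that("simulation validates its weather coverage", {
  w <- constant_weather(16, 30, start = as.Date("2022-03-01"))
  expect_error(run_simulation(w), "no 1 August")
  expect_error(run_simulation(w, sim_config(start = "2022-06-01")),
               "outside")
})
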