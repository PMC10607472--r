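# reference parameter values used throughout the tests (the packaged
# estimates for the two phases)
SDT_RATE <- lactin_params(0.16978, 22.13802, 5.67016)
SDT_DIST <- weibull_params(1.15460, 1.71717)
PUP_RATE <- lactin_params(0.151932200, 37.88922166, 6.572996371)
PUP_DIST <- weibull_params(1.121146325, 3.155020615)

# hand-written two-exponential curve for generating synthetic rates,
# independent of the package's evaluator
lactin_raw_oracle <- function(t, rho, t_max, delta_t) {
  exp(rho * t) - exp(rho * t_max - (t_max - t) / delta_t)
}

# constant-soil-temperature weather: tmin/tmax chosen so the soil-converted
# daily mean equals `soil` exactly (air mean = soil - 0.9 below the 23.3
# branch point, - 0.6 at or above it)
constant_weather <- function(soil, days, start = as.Date("2022-08-01"),
                             diurnal = 6) {
  air <- if (soil - 0.9 < 23.3) soil - 0.9 else soil - 0.6
  weather_series(start + seq_len(days) - 1L,
                 rep(air - diurnal / 2, days),
                 rep(air + diurnal / 2, days))
}

# independent oracle for the two-phase model at constant temperature:
# a direct double convolution of the two Weibull increment sequences,
# with no cohort ledger and no tail closure. Returns daily expected adult
# counts for days 1..horizon.
convolution_oracle <- function(n0, r_sdt, a_s, b_s, r_pup, a_p, b_p,
                               horizon) {
  f_s <- function(x) 1 - exp(-(x / a_s)^b_s)
  f_p <- function(x) 1 - exp(-(x / a_p)^b_p)
  transfer <- f_s(r_sdt * seq_len(horizon)) -
    f_s(r_sdt * (seq_len(horizon) - 1))
  adults <- numeric(horizon)
  for (k in seq_len(horizon - 1)) {       # cohort created on day k
    j <- (k + 1):horizon                  # develops from day k + 1
    age <- r_pup * (j - k)
    adults[j] <- adults[j] +
      n0 * transfer[k] * (f_p(age) - f_p(age - r_pup))
  }
  adults
}

# percentile day indices (fractional) of a daily emission sequence,
# interpolating the scaled cumulative sum; independent of the package's
# percentile_dates()
oracle_percentile_days <- function(daily, p) {
  cs <- cumsum(daily) / sum(daily)
  vapply(p / 100, function(q) {
    i <- which(cs >= q)[1]
    if (i == 1 || cs[i] == q) return(as.numeric(i))
    (i - 1) + (q - cs[i - 1]) / (cs[i] - cs[i - 1])
  }, numeric(1))
}
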