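#' Daily mean temperature from minimum and maximum
#'
#' @param tmin Daily minimum temperature(s), degrees C.
#' @param tmax Daily maximum temperature(s), degrees C; `tmin <= tmax`.
#' @return `(tmin + tmax) / 2`.
#' @examples
#' daily_mean(10, 20)
#' @export
daily_mean <- function(tmin, tmax) {
  stopifnot(is.numeric(tmin), is.numeric(tmax), length(tmin) == length(tmax))
  if (any(tmin > tmax, na.rm = TRUE))
    stop("'tmin' must not exceed 'tmax'", call. = FALSE)
  (tmin + tmax) / 2
}

#' Convert daily mean air temperature to soil temperature
#'
#' Empirical conversion to 5 cm soil depth for daily mean air temperatures:
#' +0.9 degrees C when the daily mean air temperature is below 23.3 degrees C,
#' +0.6 degrees C at or above 23.3 degrees C. The offset is applied per day
#' to the daily mean, which is the temperature the emergence model consumes.
#'
#' @param tmean_air Daily mean air temperature(s), degrees C. Vectorized.
#' @return Daily mean soil temperature(s), degrees C.
#' @examples
#' air_to_soil(c(20, 23.3, 25))
#' @export
air_to_soil <- function(tmean_air) {
  stopifnot(is.numeric(tmean_air))
  tmean_air + ifelse(tmean_air < 23.3, 0.9, 0.6)
}

#' Trailing moving average
#'
#' Causal moving average over the current day and the `window - 1` preceding
#' days; at the start of the series the window shrinks to the days
#' available, so the output has the same length and date alignment as the
#' input. A forecasting model cannot look ahead, hence trailing rather than
#' centred.
#'
#' @param x Numeric series.
#' @param window Window length in days, >= 1.
#' @return Numeric vector, same length as `x`.
#' @examples
#' moving_average(c(10, 16, 22), 3)
#' @export
moving_average <- function(x, window) {
  stopifnot(is.numeric(x), length(window) == 1L, window >= 1)
  window <- as.integer(window)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  s <- cumsum(x)
  out <- numeric(n)
  head_n <- seq_len(min(window, n))
  out[head_n] <- s[head_n] / head_n
  if (n > window) {
    idx <- (window + 1L):n
    out[idx] <- (s[idx] - s[idx - window]) / window
  }
  out
}

#' Construct a daily weather series
#'
#' Validates and assembles a daily weather series: dates must be strictly
#' increasing with no gaps (consecutive calendar days) and `tmin <= tmax`
#' everywhere. Derived per-day views are attached: `tmean_air`
#' ((min+max)/2), `tmean_soil` (via [air_to_soil()]) and `julian`
#' (day-of-year, 1 January = 1).
#'
#' @param date Dates (`Date` or coercible via `as.Date`).
#' @param tmin,tmax Daily minimum / maximum air temperatures, degrees C.
#' @return A data frame of class `"weather_series"` with columns `date`,
#'   `tmin_air`, `tmax_air`, `tmean_air`, `tmean_soil`, `julian`.
#' @examples
#' w <- weather_series(as.Date("2022-08-01") + 0:9, rep(18, 10), rep(28, 10))
#' head(w)
#' @export
weather_series <- function(date, tmin, tmax) {
  date <- as.Date(date)
  stopifnot(length(date) == length(tmin), length(tmin) == length(tmax),
            is.numeric(tmin), is.numeric(tmax))
  if (length(date) == 0L) stop("empty weather series", call. = FALSE)
  if (anyNA(date) || anyNA(tmin) || anyNA(tmax))
    stop("missing values in weather series", call. = FALSE)
  d <- diff(as.integer(date))
  if (any(d != 1L))
    stop("dates must be strictly increasing consecutive days; ",
         "gap or disorder near ",
         format(date[which(d != 1L)[1L] + 1L]), call. = FALSE)
  if (any(tmin > tmax))
    stop("'tmin' exceeds 'tmax' on ", format(date[which(tmin > tmax)[1L]]),
         call. = FALSE)
  tmean <- daily_mean(tmin, tmax)
  out <- data.frame(date = date, tmin_air = tmin, tmax_air = tmax,
                    tmean_air = tmean, tmean_soil = air_to_soil(tmean),
                    julian = as.POSIXlt(date)$yday + 1L)
  class(out) <- c("weather_series", "data.frame")
  out
}

#' Read a daily weather CSV
#'
#' Expects a header `date,tmin,tmax` with ISO-8601 dates and temperatures in
#' degrees C. Ordering and completeness are validated; missing dates are an
#' error, never interpolated (silent gap-filling would corrupt degree-day
#' totals).
#'
#' @param path Path to the CSV file.
#' @return A [weather_series()].
#' @export
read_weather <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin", "tmax")
  if (!all(need %in% names(x)))
    stop("weather CSV must have columns: date, tmin, tmax", call. = FALSE)
  weather_series(as.Date(x$date), x$tmin, x$tmax)
}

#' Write a weather series to CSV
#'
#' Emits the `date,tmin,tmax` dialect read by [read_weather()], optionally
#' with the derived `tmean_soil` column.
#'
#' @param series A [weather_series()].
#' @param path Output path.
#' @param soil Include the `tmean_soil` column? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_weather <- function(series, path, soil = FALSE) {
  stopifnot(inherits(series, "weather_series"))
  out <- data.frame(date = format(series$date), tmin = series$tmin_air,
                    tmax = series$tmax_air)
  if (soil) out$tmean_soil <- series$tmean_soil
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# regional presets: annual sinusoid parameters chosen to emulate (i) a warm
# maritime climate with a long stretch of soil means above the 22.1 degC
# SDT limit, (ii) a hot-summer continental climate with a shorter stretch,
# and (iii) a cool-temperate climate whose soil means rarely reach it.
.weather_profiles <- list(
  "jeju-like" = list(annual_mean = 16.8, amplitude = 10.5, peak_doy = 215,
                     diurnal_range = 6, noise_sd = 0.5),
  "jinju-like" = list(annual_mean = 13.8, amplitude = 12.0, peak_doy = 212,
                      diurnal_range = 9, noise_sd = 0.5),
  "cool-temperate" = list(annual_mean = 8.5, amplitude = 9.0, peak_doy = 200,
                          diurnal_range = 8, noise_sd = 1.0))

# run fn with a private RNG stream, restoring the caller's state
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Generate a synthetic daily weather series
#'
#' Emulates an annual temperature cycle: the daily mean is
#' `annual_mean + amplitude * cos(2*pi*(doy - peak_doy)/365)` plus iid
#' Gaussian noise, and `tmin`/`tmax` sit half the diurnal range below/above
#' it. Three presets parameterize regional summer profiles: `"jeju-like"`
#' (warm maritime; a long run -- at least 60 consecutive days -- of daily
#' soil means above the 22.1 degC diapause-termination limit),
#' `"jinju-like"` (hot continental summer, shorter exceedance) and
#' `"cool-temperate"` (soil means rarely exceed the limit). Explicit
#' parameters override the preset. Output is reproducible bit-for-bit for a
#' fixed `seed`; the caller's RNG state is left untouched.
#'
#' @param profile Preset name, or `NULL` to use explicit parameters only.
#' @param year First calendar year of the series.
#' @param n_years Number of consecutive years to generate.
#' @param annual_mean,amplitude,peak_doy,diurnal_range,noise_sd Explicit
#'   cycle parameters (degrees C, degrees C, day of year, degrees C,
#'   degrees C); any that are supplied override the preset.
#' @param seed Integer seed for the noise, or `NULL`.
#' @return A [weather_series()] covering the requested calendar years.
#' @examples
#' w <- synthetic_weather("cool-temperate", year = 2022, seed = 1)
#' range(w$tmean_soil)
#' @export
synthetic_weather <- function(profile = NULL, year = 2022, n_years = 1,
                              annual_mean = NULL, amplitude = NULL,
                              peak_doy = NULL, diurnal_range = NULL,
                              noise_sd = NULL, seed = NULL) {
  base <- list(annual_mean = 12, amplitude = 10, peak_doy = 210,
               diurnal_range = 8, noise_sd = 1)
  if (!is.null(profile)) {
    if (!profile %in% names(.weather_profiles))
      stop("unknown weather profile '", profile, "'; available: ",
           paste(names(.weather_profiles), collapse = ", "), call. = FALSE)
    base <- .weather_profiles[[profile]]
  }
  p <- list(annual_mean = annual_mean %||% base$annual_mean,
            amplitude = amplitude %||% base$amplitude,
            peak_doy = peak_doy %||% base$peak_doy,
            diurnal_range = diurnal_range %||% base$diurnal_range,
            noise_sd = noise_sd %||% base$noise_sd)
  stopifnot(p$amplitude >= 0, p$noise_sd >= 0, p$diurnal_range >= 0,
            n_years >= 1)
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year + n_years - 1)), by = "day")
  doy <- as.POSIXlt(dates)$yday + 1L
  mean_d <- p$annual_mean +
    p$amplitude * cos(2 * pi * (doy - p$peak_doy) / 365)
  noise <- with_seed(seed, function() {
    stats::rnorm(length(dates), 0, p$noise_sd)
  })
  mean_d <- mean_d + noise
  weather_series(dates, mean_d - p$diurnal_range / 2,
                 mean_d + p$diurnal_range / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
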