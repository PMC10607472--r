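#' Common lower threshold temperature
#'
#' Averages stage-specific lower developmental thresholds into a single
#' base temperature for field degree-day bookkeeping, rounded to one
#' decimal (the convention under which one day at 23 degrees C is
#' 19.1 DD).
#'
#' @param thresholds Lower threshold temperatures, degrees C, non-empty.
#' @return Common base temperature, degrees C, one decimal.
#' @examples
#' common_base_temperature(c(3.1, 3.8, 4.3, 4.0, 4.4))  # 3.9
#' @export
common_base_temperature <- function(thresholds) {
  stopifnot(is.numeric(thresholds), length(thresholds) >= 1L,
            all(is.finite(thresholds)))
  round(mean(thresholds), 1)
}

#' Thermal constant from constant-temperature development
#'
#' Degree-days required to complete a stage observed at a constant
#' temperature: `K = d * (T - t_cb)`.
#'
#' @param days Mean development time in days, positive.
#' @param temperature Incubation temperature, degrees C, above `t_cb`.
#' @param t_cb Common lower threshold temperature, degrees C.
#' @return Thermal constant in degree-days.
#' @examples
#' thermal_constant(1, 23, 3.9)  # 19.1 DD
#' @export
thermal_constant <- function(days, temperature, t_cb) {
  stopifnot(is.numeric(days), is.numeric(temperature), is.numeric(t_cb))
  if (any(days <= 0))
    stop("'days' must be positive", call. = FALSE)
  if (any(temperature <= t_cb))
    stop("'temperature' must exceed the base temperature (no development ",
         "at or below the threshold)", call. = FALSE)
  days * (temperature - t_cb)
}

#' Stage degree-day constants for Delia antiqua
#'
#' Returns the packaged thermal constants per stage (degree-days above the
#' common base temperature of 3.9 degrees C) together with the derived
#' generation totals: `egg_to_egg` (all six stages), `adult_to_pupa`
#' (pre-oviposition + egg + three larval instars, i.e. the development from
#' adult emergence to new pupae) and `backtrack` (`adult_to_pupa` minus the
#' 19.1 DD of one day at 23 degrees C, used to track adult presence
#' backwards from a late-larval collection).
#'
#' @return A list with `t_cb`, the named vector `dd`, and the scalars
#'   `egg_to_egg`, `adult_to_pupa`, `backtrack`.
#' @examples
#' stage_constants()$egg_to_egg  # 650.9
#' @export
stage_constants <- function() {
  tab <- load_fixture("stage_dd_constants")
  dd <- stats::setNames(tab$degree_days, tab$stage)
  t_cb <- common_base_temperature(load_fixture("lower_thresholds")$threshold)
  adult_to_pupa <- unname(dd[["preoviposition"]] + dd[["egg"]] +
                            dd[["instar1"]] + dd[["instar2"]] + dd[["instar3"]])
  list(t_cb = t_cb, dd = dd,
       egg_to_egg = sum(dd),
       adult_to_pupa = adult_to_pupa,
       backtrack = adult_to_pupa - thermal_constant(1, 23, t_cb))
}

#' Accumulate degree-days along a weather series
#'
#' Daily increments are `max(0, tmean_soil - t_cb)` (daily-mean-minus-base
#' with truncation at zero) accumulated from `start` to the end of the
#' series.
#'
#' @param series A [weather_series()]; soil-converted daily means drive the
#'   accumulation.
#' @param t_cb Base temperature, degrees C (default the packaged common
#'   threshold, 3.9).
#' @param start Start date (default: first date of the series); must lie
#'   within the series.
#' @return A data frame of class `"dd_track"` with columns `date`,
#'   `increment`, `cumulative`; attributes `start` and `t_cb`.
#' @examples
#' w <- synthetic_weather("jinju-like", seed = 1)
#' dd <- accumulate_dd(w, start = as.Date("2022-10-01"))
#' tail(dd, 2)
#' @export
accumulate_dd <- function(series, t_cb = 3.9, start = NULL) {
  stopifnot(inherits(series, "weather_series"))
  if (is.null(start)) start <- series$date[1L]
  start <- as.Date(start)
  if (start < series$date[1L] || start > series$date[nrow(series)])
    stop("'start' lies outside the weather series", call. = FALSE)
  sub <- series[series$date >= start, , drop = FALSE]
  inc <- pmax(0, sub$tmean_soil - t_cb)
  out <- data.frame(date = sub$date, increment = inc,
                    cumulative = cumsum(inc))
  attr(out, "start") <- start
  attr(out, "t_cb") <- t_cb
  class(out) <- c("dd_track", "data.frame")
  out
}

#' Date at which a degree-day target is first reached
#'
#' Returns the first date whose cumulative degree-days meet or exceed
#' `target` (whole-day resolution, no sub-day interpolation). If the target
#' is never reached within the series -- development not completed that
#' season -- `NA` is returned (as a `Date`) with a warning.
#'
#' @param track A `"dd_track"` from [accumulate_dd()].
#' @param target Degree-day target, >= 0.
#' @return A `Date` (the start date when `target` is 0), or `NA` if the
#'   target is not reached.
#' @examples
#' w <- synthetic_weather("jinju-like", seed = 1)
#' date_at_dd(accumulate_dd(w, start = as.Date("2022-08-01")), 650.9)
#' @export
date_at_dd <- function(track, target) {
  stopifnot(inherits(track, "dd_track"), is.numeric(target),
            length(target) == 1L, target >= 0)
  if (target == 0) return(attr(track, "start"))
  idx <- which(track$cumulative >= target)
  if (length(idx) == 0L) {
    warning("degree-day target ", target,
            " not reached by the end of the series (",
            round(track$cumulative[nrow(track)], 1),
            " DD accumulated): not completed this season", call. = FALSE)
    return(as.Date(NA))
  }
  track$date[idx[1L]]
}

#' Backward degree-day tracking from an end date
#'
#' Finds the latest date `d` such that the degree-days accumulated on the
#' days strictly after `d` through `end` reach `target` -- i.e. development
#' starting the day after `d` completes by `end`. This is the inverse of
#' forward tracking at daily resolution: re-accumulating forward from the
#' returned date reaches the target no later than `end` (within one day).
#'
#' @param series A [weather_series()].
#' @param end End date, within the series.
#' @param target Degree-day target, >= 0.
#' @param t_cb Base temperature, degrees C.
#' @return A `Date` (`end` itself when `target` is 0), or `NA` with a
#'   warning if the series before `end` is too cold to accumulate `target`.
#' @examples
#' w <- synthetic_weather("jinju-like", seed = 1)
#' backtrack_date(w, as.Date("2022-11-24"), 414.8)
#' @export
backtrack_date <- function(series, end, target, t_cb = 3.9) {
  stopifnot(inherits(series, "weather_series"), is.numeric(target),
            length(target) == 1L, target >= 0)
  end <- as.Date(end)
  if (end < series$date[1L] || end > series$date[nrow(series)])
    stop("'end' lies outside the weather series", call. = FALSE)
  if (target == 0) return(end)
  sub <- series[series$date <= end, , drop = FALSE]
  inc <- pmax(0, sub$tmean_soil - t_cb)
  n <- length(inc)
  # after[i] = DD accumulated on days strictly after date i through end
  after <- rev(cumsum(rev(inc))) - inc
  idx <- which(after >= target)
  if (length(idx) == 0L) {
    warning("degree-day target ", target, " cannot be accumulated before ",
            format(end), call. = FALSE)
    return(as.Date(NA))
  }
  sub$date[idx[length(idx)]]
}
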