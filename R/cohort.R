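#' Simulation configuration for the two-phase emergence model
#'
#' Bundles the parameters of the daily cohort simulation: the initial
#' aestivating cohort (1000 pupae, all at physiological age 0), the start
#' date (1 August, the hottest season), the summer-diapause-termination
#' (SDT) rate curve and completion distribution, the non-diapausing pupal
#' development-rate curve and development-time distribution, and the
#' tail-closure threshold at which a cohort's residual is transferred in
#' full (the Weibull CDF never reaches 1, so an untreated tail would leak
#' mass past any finite horizon).
#'
#' @param start Start date, or `NULL` to use the first 1 August in the
#'   weather series.
#' @param n0 Initial aestivating cohort size, positive.
#' @param sdt Phase-I models: a list with `rate` ([lactin_params()]) and
#'   `dist` ([weibull_params()]); default [sdt_defaults()].
#' @param pupal Phase-II models, same structure; default [pupal_defaults()].
#' @param tail_threshold CDF level above which a cohort is closed out
#'   (default 0.999).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(start = NULL, n0 = 1000, sdt = sdt_defaults(),
                       pupal = pupal_defaults(), tail_threshold = 0.999) {
  stopifnot(is.numeric(n0), length(n0) == 1L, n0 > 0,
            inherits(sdt$rate, "lactin_params"),
            inherits(sdt$dist, "weibull_params"),
            inherits(pupal$rate, "lactin_params"),
            inherits(pupal$dist, "weibull_params"),
            tail_threshold > 0, tail_threshold < 1)
  if (!is.null(start)) start <- as.Date(start)
  structure(list(start = start, n0 = n0, sdt = sdt, pupal = pupal,
                 tail_threshold = tail_threshold), class = "sim_config")
}

#' Initial state of the cohort simulation
#'
#' One aestivating cohort of `config$n0` pupae at physiological age 0 and
#' no pupal cohorts. The state is advanced one day at a time by
#' [step_day()].
#'
#' @param config A [sim_config()].
#' @return An object of class `"sim_state"`.
#' @export
sim_state <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  structure(list(
    config = config,
    day = 0L,
    aest = list(x = 0, cdf = 0, active = TRUE),
    pupal = data.frame(created = integer(0), px = numeric(0),
                       cdf = numeric(0), count0 = numeric(0)),
    adults_cum = 0,
    today = NULL), class = "sim_state")
}

#' Advance the cohort simulation by one day
#'
#' One 24 h step of the two-phase model, in fixed order:
#' (a) Phase I -- the aestivating cohort's physiological age advances by the
#' SDT rate evaluated at the 3-day moving-average soil temperature, and the
#' CDF increment of the completion distribution transfers that fraction of
#' the initial cohort into a new pupal cohort dated today (age reset to 0);
#' (b) Phase II -- every pupal cohort created on a previous day advances by
#' the pupal rate at today's mean soil temperature and emits its CDF
#' increment as newly emerged adults. A cohort never advances on its
#' creation day (no double progress within one step). Cohorts whose CDF
#' exceeds the tail threshold transfer their entire residual and retire, so
#' mass is conserved exactly: aestivating + pupal + emerged = `n0` every
#' day. Fractional individuals are carried as real numbers (the model is a
#' deterministic expectation).
#'
#' @param state A `"sim_state"` from [sim_state()] or a previous step.
#' @param t3d_soil 3-day trailing moving average of daily mean soil
#'   temperature, degrees C (drives Phase I).
#' @param tmean_soil Today's daily mean soil temperature, degrees C
#'   (drives Phase II).
#' @return The updated state; `state$today` holds the day's bookkeeping
#'   (`transferred`, `adults_new`, `aestivating`, `pupae`, `adults_cum`).
#' @examples
#' st <- sim_state(sim_config(n0 = 1000))
#' st <- step_day(st, t3d_soil = 16, tmean_soil = 16)
#' st$today$transferred  # fraction of cohort leaving diapause, times n0
#' @export
step_day <- function(state, t3d_soil, tmean_soil) {
  stopifnot(inherits(state, "sim_state"),
            is.finite(t3d_soil), is.finite(tmean_soil))
  cfg <- state$config
  state$day <- state$day + 1L

  # Phase I: summer-diapause termination
  transferred <- 0
  if (state$aest$active) {
    x_new <- state$aest$x + lactin_rate(t3d_soil, cfg$sdt$rate)
    cdf_new <- weibull_cdf(x_new, cfg$sdt$dist)
    if (cdf_new > cfg$tail_threshold) {
      frac <- 1 - state$aest$cdf
      state$aest$active <- FALSE
      cdf_new <- 1
    } else {
      frac <- cdf_new - state$aest$cdf
    }
    state$aest$x <- x_new
    state$aest$cdf <- cdf_new
    transferred <- cfg$n0 * frac
    if (frac > 0) {
      state$pupal <- rbind(state$pupal,
                           data.frame(created = state$day, px = 0, cdf = 0,
                                      count0 = transferred))
    }
  }

  # Phase II: development of pupal cohorts created on previous days
  adults_new <- 0
  if (nrow(state$pupal) > 0L) {
    old <- state$pupal$created < state$day
    if (any(old)) {
      px_new <- state$pupal$px[old] + lactin_rate(tmean_soil, cfg$pupal$rate)
      cdf_new <- weibull_cdf(px_new, cfg$pupal$dist)
      close <- cdf_new > cfg$tail_threshold
      emit_frac <- ifelse(close, 1 - state$pupal$cdf[old],
                          cdf_new - state$pupal$cdf[old])
      adults_new <- sum(state$pupal$count0[old] * emit_frac)
      state$pupal$px[old] <- px_new
      state$pupal$cdf[old] <- ifelse(close, 1, cdf_new)
      drop <- old
      drop[old] <- close
      if (any(drop)) state$pupal <- state$pupal[!drop, , drop = FALSE]
    }
  }
  state$adults_cum <- state$adults_cum + adults_new

  state$today <- list(
    transferred = transferred,
    adults_new = adults_new,
    aestivating = if (state$aest$active) cfg$n0 * (1 - state$aest$cdf) else 0,
    pupae = if (nrow(state$pupal)) {
      sum(state$pupal$count0 * (1 - state$pupal$cdf))
    } else 0,
    adults_cum = state$adults_cum)
  state
}

#' Run the two-phase daily emergence simulation
#'
#' Simulates adult emergence of *D. antiqua* from a summer-diapausing pupal
#' cohort under a daily weather series. Daily mean air temperatures are
#' converted to soil temperatures; Phase I (diapause termination) is driven
#' by the trailing 3-day moving average of soil means (computed over the
#' full series, so days before the start date stabilize the window) and
#' Phase II (pupal development) by the same-day soil mean. The simulation
#' starts on `config$start` (default: the first 1 August in the series) and
#' runs to the end of the series, iterating [step_day()].
#'
#' @param weather A [weather_series()] covering the start date onwards.
#' @param config A [sim_config()].
#' @return An object of class `"emergence_sim"`: `daily` (data frame with
#'   `date`, `julian`, `t3d_soil`, `tmean_soil`, `aestivating`, `pupae`,
#'   `adults_new`, `adults_cum`), `config`, `start`, `total_emerged`.
#'   Methods: `print`, `summary`, `plot`, [simulate()][simulate.emergence_sim].
#' @examples
#' w <- synthetic_weather("jinju-like", year = 2022, seed = 42)
#' sim <- run_simulation(w, sim_config())
#' summary(sim)
#' @export
run_simulation <- function(weather, config = sim_config()) {
  stopifnot(inherits(weather, "weather_series"),
            inherits(config, "sim_config"))
  start <- config$start
  if (is.null(start)) {
    aug1 <- weather$date[format(weather$date, "%m-%d") == "08-01"]
    if (length(aug1) == 0L)
      stop("no 1 August in the weather series; give 'start' explicitly",
           call. = FALSE)
    start <- aug1[1L]
  }
  if (start < weather$date[1L] || start > weather$date[nrow(weather)])
    stop("simulation start ", format(start),
         " lies outside the weather series", call. = FALSE)

  t3d <- moving_average(weather$tmean_soil, 3L)
  idx <- which(weather$date >= start)
  state <- sim_state(config)
  n <- length(idx)
  daily <- data.frame(date = weather$date[idx],
                      julian = weather$julian[idx],
                      t3d_soil = t3d[idx],
                      tmean_soil = weather$tmean_soil[idx],
                      aestivating = numeric(n), pupae = numeric(n),
                      adults_new = numeric(n), adults_cum = numeric(n))
  for (i in seq_len(n)) {
    state <- step_day(state, t3d[idx[i]], weather$tmean_soil[idx[i]])
    daily$aestivating[i] <- state$today$aestivating
    daily$pupae[i] <- state$today$pupae
    daily$adults_new[i] <- state$today$adults_new
    daily$adults_cum[i] <- state$today$adults_cum
  }
  structure(list(daily = daily, config = config, start = start,
                 total_emerged = state$adults_cum),
            class = "emergence_sim")
}

#' @export
print.emergence_sim <- function(x, ...) {
  cat(sprintf("Two-phase emergence simulation: %d days from %s\n",
              nrow(x$daily), format(x$start)))
  cat(sprintf("  initial cohort %g; emerged %.1f adults (%.1f%%)\n",
              x$config$n0, x$total_emerged,
              100 * x$total_emerged / x$config$n0))
  invisible(x)
}

#' @export
summary.emergence_sim <- function(object, ...) {
  print(object)
  if (object$total_emerged > 0) {
    cv <- emergence_curve(object)
    pct <- c(10, 50, 90)
    reach <- pct[pct <= 100 * max(cv$fraction)]
    if (length(reach)) {
      jd <- percentile_dates(cv, reach)
      cat("  emergence percentile dates (Julian):\n")
      for (i in seq_along(reach))
        cat(sprintf("    %3d%%: %.1f\n", reach[i], jd[i]))
    }
  }
  invisible(object)
}

#' @export
plot.emergence_sim <- function(x, ...) {
  d <- x$daily
  graphics::plot(d$date, d$adults_new, type = "h",
                 xlab = "Date", ylab = "Newly emerged adults / day",
                 main = "Predicted adult emergence", ...)
  invisible(x)
}

#' Cumulative emergence curve scaled to the total
#'
#' Accumulates daily adult emergence and scales by the final cumulative
#' total, giving a non-decreasing curve that ends at 1. With zero total
#' emergence an explicit empty curve (zero rows) is returned.
#'
#' @param result An `"emergence_sim"` from [run_simulation()].
#' @return A data frame of class `"emergence_curve"` with columns `date`,
#'   `julian`, `fraction`.
#' @export
emergence_curve <- function(result) {
  stopifnot(inherits(result, "emergence_sim"))
  d <- result$daily
  if (result$total_emerged <= 0) {
    out <- data.frame(date = as.Date(character(0)), julian = numeric(0),
                      fraction = numeric(0))
  } else {
    # day-of-year relative to 1 January of the start year, continuing past
    # 365 if the simulation runs into the next calendar year, so the date
    # axis never wraps
    jd <- as.integer(d$date -
                       as.Date(format(d$date[1L], "%Y-01-01"))) + 1L
    out <- data.frame(date = d$date, julian = jd,
                      fraction = d$adults_cum / result$total_emerged)
  }
  class(out) <- c("emergence_curve", "data.frame")
  out
}

#' Individual-based Monte Carlo realization of the emergence model
#'
#' Stochastic counterpart of the deterministic cohort expectation: each of
#' `n` individuals draws a diapause-termination threshold and a pupal
#' development threshold from the two Weibull distributions over
#' physiological age, and advances by the same daily rates under the same
#' weather (termination the day cumulative SDT age crosses the first
#' threshold; pupal age accumulating from the following day; emergence the
#' day it crosses the second). As `n` grows the realized daily emergence
#' distribution converges to the cohort model's.
#'
#' @param object An `"emergence_sim"` (supplies weather drivers and
#'   parameters).
#' @param nsim Number of replicate realizations (columns), default 1.
#' @param seed Integer seed, or `NULL`.
#' @param n Individuals per realization, default 10000.
#' @param ... Unused.
#' @return A data frame with `date`, `julian` and one `adults_new.k` count
#'   column per replicate; attribute `emerged` gives each replicate's total.
#' @examples
#' w <- synthetic_weather("jinju-like", year = 2022, seed = 42)
#' sim <- run_simulation(w, sim_config())
#' mc <- simulate(sim, seed = 7, n = 2000)
#' sum(mc$adults_new.1)
#' @export
simulate.emergence_sim <- function(object, nsim = 1, seed = NULL,
                                   n = 10000, ...) {
  stopifnot(nsim >= 1, n >= 1)
  cfg <- object$config
  d <- object$daily
  ndays <- nrow(d)
  cum_s <- cumsum(lactin_rate(d$t3d_soil, cfg$sdt$rate))
  cum_p <- c(0, cumsum(lactin_rate(d$tmean_soil, cfg$pupal$rate)))

  one_run <- function() {
    thr_s <- stats::rweibull(n, shape = cfg$sdt$dist$beta,
                             scale = cfg$sdt$dist$alpha)
    thr_p <- stats::rweibull(n, shape = cfg$pupal$dist$beta,
                             scale = cfg$pupal$dist$alpha)
    # day index at which cumulative SDT age first reaches the threshold
    term_day <- findInterval(thr_s, cum_s, left.open = TRUE) + 1L
    alive <- term_day <= ndays
    emerge_day <- rep(NA_integer_, n)
    for (dd in unique(term_day[alive])) {
      sel <- alive & term_day == dd
      # pupal age on day j is cum_p[j + 1] - cum_p[dd + 1] (advance starts
      # the day after creation)
      tgt <- thr_p[sel] + cum_p[dd + 1L]
      ed <- findInterval(tgt, cum_p, left.open = TRUE)
      ed[ed > ndays] <- NA_integer_
      emerge_day[sel] <- ed
    }
    tabulate(emerge_day[!is.na(emerge_day)], nbins = ndays)
  }

  counts <- with_seed(seed, function() {
    replicate(nsim, one_run(), simplify = FALSE)
  })
  out <- data.frame(date = d$date, julian = d$julian)
  for (k in seq_len(nsim)) out[[paste0("adults_new.", k)]] <- counts[[k]]
  attr(out, "emerged") <- vapply(counts, sum, numeric(1))
  out
}
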