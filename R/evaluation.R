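#' Coerce to a cumulative emergence curve
#'
#' Accepts an existing `"emergence_curve"`, an `"emergence_sim"` (via
#' [emergence_curve()]), or a data frame with a `julian` (or `date`) column
#' and one of `fraction` (cumulative fractions in `[0, 1]`), `percent`
#' (cumulative percentages, e.g. percentile--date pairs from a field table)
#' or `count` (raw cumulative counts, scaled by their maximum). Fractions
#' must be non-decreasing and dates strictly increasing.
#'
#' @param x Object to coerce.
#' @return A data frame of class `"emergence_curve"` with columns `julian`
#'   and `fraction` (plus `date` when available).
#' @examples
#' as_emergence_curve(data.frame(julian = c(260, 262), percent = c(40, 60)))
#' @export
as_emergence_curve <- function(x) {
  if (inherits(x, "emergence_curve")) return(x)
  if (inherits(x, "emergence_sim")) return(emergence_curve(x))
  stopifnot(is.data.frame(x))
  out <- data.frame(julian = if ("julian" %in% names(x)) x$julian
                    else as.POSIXlt(as.Date(x$date))$yday + 1)
  if ("date" %in% names(x)) out$date <- as.Date(x$date)
  if ("fraction" %in% names(x)) out$fraction <- x$fraction
  else if ("percent" %in% names(x)) out$fraction <- x$percent / 100
  else if ("count" %in% names(x)) out$fraction <- x$count / max(x$count)
  else stop("need a 'fraction', 'percent' or 'count' column", call. = FALSE)
  if (any(out$fraction < 0 | out$fraction > 1))
    stop("cumulative fractions must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(out$julian, strictly = TRUE))
    stop("dates must be strictly increasing", call. = FALSE)
  if (is.unsorted(out$fraction))
    stop("cumulative fractions must be non-decreasing", call. = FALSE)
  class(out) <- c("emergence_curve", "data.frame")
  out
}

#' Dates at which an emergence curve crosses given percentiles
#'
#' Linear interpolation between the two observations bracketing each
#' requested cumulative-emergence percentile. An exact hit returns that
#' date; a percentile already met at the first point returns the first
#' date; a percentile above the curve's maximum is an error (not reached).
#'
#' @param curve Anything [as_emergence_curve()] accepts.
#' @param percentiles Cumulative-emergence percentages in `(0, 100]`.
#' @return Fractional Julian dates, one per percentile.
#' @examples
#' cv <- data.frame(julian = c(260, 262), percent = c(40, 60))
#' percentile_dates(cv, 50)  # 261
#' @export
percentile_dates <- function(curve, percentiles) {
  curve <- as_emergence_curve(curve)
  stopifnot(is.numeric(percentiles), all(percentiles > 0))
  if (nrow(curve) == 0L)
    stop("empty emergence curve: no emergence occurred", call. = FALSE)
  fmax <- max(curve$fraction)
  vapply(percentiles / 100, function(p) {
    if (p > fmax)
      stop(sprintf("percentile %g%% not reached (curve tops out at %.1f%%)",
                   100 * p, 100 * fmax), call. = FALSE)
    i <- which(curve$fraction >= p)[1L]
    if (i == 1L || curve$fraction[i] == p) return(curve$julian[i])
    f0 <- curve$fraction[i - 1L]
    f1 <- curve$fraction[i]
    curve$julian[i - 1L] +
      (p - f0) / (f1 - f0) * (curve$julian[i] - curve$julian[i - 1L])
  }, numeric(1))
}

#' Compare observed and predicted emergence curves
#'
#' Extracts the dates at which both curves cross the requested cumulative
#' emergence percentiles, takes the absolute per-percentile date
#' differences in days, and tests the mean absolute discrepancy against a
#' null value (default 5 days) with a two-sided one-sample t-test
#' (SE = sd/sqrt(n) with the n-1 denominator; df = n - 1; the t statistic
#' is positive when the mean discrepancy exceeds the null). With fewer than
#' two percentiles only the mean is reported.
#'
#' @param observed,predicted Anything [as_emergence_curve()] accepts; both
#'   must reach the largest requested percentile.
#' @param percentiles Percentages at which to pair dates; default
#'   `c(10, 15, 25, 50, 75, 90, 95)`.
#' @param null_days Null mean discrepancy in days, default 5.
#' @return An object of class `"emergence_comparison"`: `table` (percent,
#'   observed, predicted, difference), `mean_difference`, `se`,
#'   `t_statistic`, `p_value`, `df`, `null_days`, `significant` (at 0.05).
#' @examples
#' obs <- data.frame(julian = c(250, 260, 270), percent = c(5, 50, 100))
#' pred <- data.frame(julian = c(255, 265, 275), percent = c(5, 50, 100))
#' compare_emergence(obs, pred, percentiles = c(25, 50, 75))
#' @export
compare_emergence <- function(observed, predicted,
                              percentiles = c(10, 15, 25, 50, 75, 90, 95),
                              null_days = 5) {
  obs <- percentile_dates(observed, percentiles)
  prd <- percentile_dates(predicted, percentiles)
  diffs <- abs(obs - prd)
  n <- length(diffs)
  m <- mean(diffs)
  if (n >= 2L) {
    se <- stats::sd(diffs) / sqrt(n)
    if (se == 0) {
      # degenerate case: every percentile shows the same discrepancy
      tval <- if (m == null_days) 0 else sign(m - null_days) * Inf
      pval <- if (tval == 0) 1 else 0
    } else {
      tval <- (m - null_days) / se
      pval <- 2 * stats::pt(-abs(tval), df = n - 1L)
    }
  } else {
    se <- tval <- pval <- NA_real_
  }
  structure(list(
    table = data.frame(percent = percentiles, observed = obs,
                       predicted = prd, difference = diffs),
    mean_difference = m, se = se, t_statistic = tval, p_value = pval,
    df = n - 1L, null_days = null_days,
    significant = is.finite(pval) && pval < 0.05),
    class = "emergence_comparison")
}

#' @export
print.emergence_comparison <- function(x, ...) {
  cat("Observed vs predicted cumulative-emergence dates (Julian)\n")
  print(transform(x$table, observed = round(observed, 1),
                  predicted = round(predicted, 1),
                  difference = round(difference, 1)), row.names = FALSE)
  cat(sprintf("Mean |difference| = %.2f d, SE = %.4f\n",
              x$mean_difference, x$se))
  if (is.finite(x$t_statistic))
    cat(sprintf("t = %.4f (df = %d) vs null of %g d: p = %.4f %s\n",
                x$t_statistic, x$df, x$null_days, x$p_value,
                if (x$significant) "*" else "ns"))
  invisible(x)
}
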