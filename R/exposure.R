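#' Through-origin fit of diapause-termination proportion versus exposure
#'
#' At a constant temperature, the proportion of a pupal cohort that has
#' terminated summer diapause grows approximately linearly with exposure
#' time, with no termination at zero exposure. This fits the through-origin
#' line `y = a x` by least squares and derives the 50\% completion time
#' `P50 = 1 / (2 a)` -- by interpolation within the observed exposure range
#' or extrapolation beyond it. A non-positive slope is flagged invalid
#' (no detectable termination at that temperature).
#'
#' @param exposure_days Exposure periods in days, strictly positive,
#'   length >= 2.
#' @param proportion Completed proportions in `[0, 1]`, same length.
#' @param temperature Optional treatment temperature (degrees C), recorded
#'   in the result.
#' @return An object of class `"exposure_fit"`: `temperature`, `slope`
#'   (proportion/day), `p50` (days; `NA` when invalid), `valid`,
#'   `fitted.values`, `residuals`, `data`.
#' @examples
#' fit_exposure(c(1, 2, 5), c(0.1, 0.2, 0.5))  # slope 0.1, P50 = 5 d
#' @export
fit_exposure <- function(exposure_days, proportion, temperature = NA_real_) {
  stopifnot(is.numeric(exposure_days), is.numeric(proportion),
            length(exposure_days) == length(proportion))
  if (length(exposure_days) < 2L)
    stop("at least 2 assay points are required", call. = FALSE)
  if (any(exposure_days <= 0))
    stop("'exposure_days' must be strictly positive", call. = FALSE)
  if (any(proportion < 0 | proportion > 1))
    stop("'proportion' values must lie in [0, 1]", call. = FALSE)

  fit <- stats::lm(proportion ~ 0 + exposure_days)
  a <- unname(stats::coef(fit)[1L])
  valid <- is.finite(a) && a > 0
  structure(list(
    temperature = temperature,
    slope = a,
    p50 = if (valid) 1 / (2 * a) else NA_real_,
    valid = valid,
    fitted.values = unname(stats::fitted(fit)),
    residuals = unname(stats::residuals(fit)),
    data = data.frame(exposure_days = exposure_days,
                      proportion = proportion)),
    class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat("Through-origin exposure fit")
  if (is.finite(x$temperature)) cat(sprintf(" at %.1f degC", x$temperature))
  cat("\n")
  if (x$valid)
    cat(sprintf("  slope a = %.5g /day;  P50 = %.4g days\n", x$slope, x$p50))
  else
    cat("  invalid fit: non-positive slope (no detectable termination)\n")
  invisible(x)
}

#' @export
coef.exposure_fit <- function(object, ...) c(slope = object$slope)

#' Normalize exposure times by the 50\% completion period
#'
#' Divides exposure times (days) by the temperature-specific `P50` so that
#' completion data from different temperatures share a dimensionless time
#' axis centred on 1 at 50\% completion.
#'
#' @param days Exposure times in days (may be empty).
#' @param p50 50\% completion period in days, positive.
#' @return Dimensionless normalized times, same length as `days`.
#' @examples
#' normalize_times(c(1, 2, 5), 2)
#' @export
normalize_times <- function(days, p50) {
  stopifnot(is.numeric(days), is.numeric(p50), length(p50) == 1L)
  if (!is.finite(p50) || p50 <= 0)
    stop("'p50' must be positive", call. = FALSE)
  days / p50
}
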