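#' Daily completion-density surface over temperature and time
#'
#' For each constant temperature, physiological age is accumulated daily at
#' the Lactin rate and the Weibull completion distribution converts it into
#' the fraction of the cohort completing on each day: entry (T, i) is
#' CDF(x_i) - CDF(x_{i-1}) with x_i = i * r(T). Rows at temperatures at or
#' above the thermal maximum are all zero (arrested development); every row
#' is non-negative and sums to at most 1.
#'
#' @param params A [lactin_params()] rate curve.
#' @param dist A [weibull_params()] completion distribution.
#' @param temperatures Constant temperatures (degrees C), one per row.
#' @param horizon Number of days (columns), >= 1.
#' @return A numeric matrix with `length(temperatures)` rows and `horizon`
#'   columns of daily completion fractions; dimnames give temperature and
#'   day.
#' @examples
#' s <- sdt_defaults()
#' surf <- density_surface(s$rate, s$dist, c(10, 16, 25), horizon = 10)
#' rowSums(surf)
#' @export
density_surface <- function(params, dist, temperatures, horizon) {
  stopifnot(inherits(params, "lactin_params"),
            inherits(dist, "weibull_params"),
            is.numeric(temperatures), length(temperatures) >= 1L,
            is.numeric(horizon), length(horizon) == 1L, horizon >= 1)
  horizon <- as.integer(horizon)
  r <- lactin_rate(temperatures, params)
  out <- t(vapply(r, function(ri) {
    diff(weibull_cdf(ri * (0:horizon), dist))
  }, numeric(horizon)))
  dimnames(out) <- list(temperature = format(temperatures),
                        day = seq_len(horizon))
  out
}
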