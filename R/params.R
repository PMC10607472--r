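#' Lactin thermal-response parameters
#'
#' Container for the three parameters of the Lactin temperature-dependent
#' rate curve \eqn{r(T) = e^{\rho T} - e^{\rho T_m - (T_m - T)/\Delta T}}
#' (clamped at zero): `rho`, the composite rate coefficient for the
#' enzyme-catalysed reactions driving development; `t_max`, the thermal
#' maximum in degrees C at which the rate is exactly zero; and `delta_t`,
#' the thermal-breakdown range in degrees C over which high-temperature
#' inactivation dominates.
#'
#' @param rho Composite rate coefficient (1/degree C scale).
#' @param t_max Thermal maximum (degrees C); the rate is zero at `t_max`.
#' @param delta_t Thermal-breakdown range (degrees C); must be positive.
#' @return An object of class `"lactin_params"`.
#' @seealso [lactin_rate()], [fit_lactin()]
#' @examples
#' p <- lactin_params(rho = 0.16978, t_max = 22.13802, delta_t = 5.67016)
#' lactin_rate(16, p)
#' @export
lactin_params <- function(rho, t_max, delta_t) {
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho),
            is.numeric(t_max), length(t_max) == 1L, is.finite(t_max),
            is.numeric(delta_t), length(delta_t) == 1L, is.finite(delta_t))
  if (delta_t <= 0)
    stop("'delta_t' must be positive", call. = FALSE)
  structure(list(rho = rho, t_max = t_max, delta_t = delta_t),
            class = "lactin_params")
}

#' @export
print.lactin_params <- function(x, ...) {
  cat("Lactin thermal-response parameters\n")
  cat(sprintf("  rho     = %.6g\n  t_max   = %.6g degC\n  delta_t = %.6g degC\n",
              x$rho, x$t_max, x$delta_t))
  invisible(x)
}

#' Weibull completion-time distribution parameters
#'
#' Two-parameter Weibull distribution over normalized (physiological) age,
#' used to spread individual completion times around a cohort's mean
#' physiological age: `alpha` is the dimensionless scale (the transition
#' centre -- the CDF equals 1 - exp(-1) = 63.2\% at `alpha`) and `beta` the
#' shape (steepness of the transition).
#'
#' @param alpha Scale parameter (dimensionless), positive.
#' @param beta Shape parameter (dimensionless), positive.
#' @return An object of class `"weibull_params"`.
#' @seealso [weibull_cdf()], [fit_weibull()]
#' @examples
#' d <- weibull_params(alpha = 1.1546, beta = 1.71717)
#' weibull_cdf(d$alpha, d)  # 0.632
#' @export
weibull_params <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (alpha <= 0 || beta <= 0)
    stop("'alpha' and 'beta' must be positive", call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat("Weibull completion-time distribution\n")
  cat(sprintf("  alpha = %.6g (transition centre)\n  beta  = %.6g (steepness)\n",
              x$alpha, x$beta))
  invisible(x)
}

#' Reference model parameters for Delia antiqua
#'
#' Published parameter estimates distributed with the package: the
#' summer-diapause-termination (SDT) rate curve and completion-time
#' distribution (`sdt_defaults()`), and the non-diapausing pupal
#' development-rate curve and development-time distribution
#' (`pupal_defaults()`). These are read from the packaged fixture tables
#' and are the default parameter sets of [sim_config()].
#'
#' @return A list with components `rate` (a [lactin_params()] object) and
#'   `dist` (a [weibull_params()] object).
#' @examples
#' sdt_defaults()$rate
#' pupal_defaults()$dist
#' @export
sdt_defaults <- function() {
  tab <- load_fixture("sdt_model_params")
  est <- stats::setNames(tab$estimate, tab$parameter)
  list(rate = lactin_params(est[["rho"]], est[["t_max"]], est[["delta_t"]]),
       dist = weibull_params(est[["alpha"]], est[["beta"]]))
}

#' @rdname sdt_defaults
#' @export
pupal_defaults <- function() {
  tab <- load_fixture("pupal_model_params")
  est <- stats::setNames(tab$estimate, tab$parameter)
  list(rate = lactin_params(est[["rho"]], est[["t_max"]], est[["delta_t"]]),
       dist = weibull_params(est[["alpha"]], est[["beta"]]))
}
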