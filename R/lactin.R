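#' Lactin temperature-dependent development rate
#'
#' Evaluates the Lactin rate curve
#' \eqn{r(T) = e^{\rho T} - e^{\rho T_m - (T_m - T)/\Delta T}} and clamps
#' negative values to zero, so the rate is exactly zero at the thermal
#' maximum `t_max` and above it. The curve is continuous in `t`.
#'
#' @param t Temperature(s), degrees C. Vectorized.
#' @param params A [lactin_params()] object.
#' @return Development rate(s) per day, non-negative.
#' @examples
#' p <- lactin_params(0.16978, 22.13802, 5.67016)
#' lactin_rate(c(10, 16, 22.13802, 30), p)
#' @export
lactin_rate <- function(t, params) {
  stopifnot(inherits(params, "lactin_params"), is.numeric(t))
  pmax(0, lactin_raw(t, params$rho, params$t_max, params$delta_t))
}

# unclamped two-exponential expression; used for fitting and root-finding
lactin_raw <- function(t, rho, t_max, delta_t) {
  exp(rho * t) - exp(rho * t_max - (t_max - t) / delta_t)
}

#' Upper temperature limit of a Lactin rate curve
#'
#' Finds the upper zero of the (unclamped) Lactin expression above the
#' curve's peak by root-finding: the temperature at which development is
#' arrested. For the summer-diapause-termination curve of *D. antiqua*
#' this is the critical temperature of the hot summer effect
#' (about 22.1 degrees C with the reference parameters).
#'
#' @param params A [lactin_params()] object.
#' @param tol Root-finding tolerance, degrees C.
#' @return Temperature (degrees C) at which the rate falls to zero.
#' @examples
#' lactin_upper_limit(sdt_defaults()$rate)
#' @export
lactin_upper_limit <- function(params, tol = 1e-8) {
  stopifnot(inherits(params, "lactin_params"))
  f <- function(t) lactin_raw(t, params$rho, params$t_max, params$delta_t)
  pk <- stats::optimize(f, interval = c(params$t_max - 60, params$t_max),
                        maximum = TRUE)
  hi <- params$t_max + 50
  if (f(pk$maximum) <= 0 || f(hi) >= 0)
    stop("rate curve has no upper zero above its peak", call. = FALSE)
  stats::uniroot(f, c(pk$maximum, hi), tol = tol)$root
}

#' Fit the Lactin rate curve by least squares
#'
#' Fits the three-parameter Lactin curve to observed development rates by
#' unweighted nonlinear least squares. Starting values come from a
#' deterministic coarse grid (`rho` 0.05--0.30 by 0.025, `t_max` from the
#' highest observed temperature to +20 degrees C by 2, `delta_t` 1--10 by 1);
#' the best starts are refined by Levenberg--Marquardt and the lowest
#' residual sum of squares wins, ties broken by the lowest `rho`. The fit is
#' therefore reproducible without a random seed. R-squared is
#' 1 - SSE/SST about the mean observed rate.
#'
#' @param temperature Temperatures, degrees C (length >= 4).
#' @param rate Observed development rates (per day), same length.
#' @param n_starts Number of best grid points refined (default 15).
#' @return An object of class `"lactin_fit"` with components `params`
#'   (a [lactin_params()]), `coefficients`, `fitted.values`, `residuals`,
#'   `r.squared`, `sse` and `data`. Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' dev <- load_fixture("pupal_development_points")
#' fit <- fit_lactin(dev$temperature, 1 / dev$days)
#' coef(fit)
#' fit$r.squared
#' @export
fit_lactin <- function(temperature, rate, n_starts = 15L) {
  stopifnot(is.numeric(temperature), is.numeric(rate),
            length(temperature) == length(rate),
            all(is.finite(temperature)), all(is.finite(rate)))
  if (length(temperature) < 4L)
    stop("at least 4 (temperature, rate) points are required", call. = FALSE)
  if (length(unique(temperature)) < 3L)
    stop("temperatures must span a rising region of the curve", call. = FALSE)

  t_hi <- max(temperature)
  grid <- expand.grid(rho = seq(0.05, 0.30, by = 0.025),
                      t_max = seq(t_hi, t_hi + 20, by = 2),
                      delta_t = seq(1, 10, by = 1))
  sse_at <- function(p) {
    r <- rate - lactin_raw(temperature, p[1L], p[2L], p[3L])
    if (all(is.finite(r))) sum(r^2) else Inf
  }
  grid$sse <- apply(grid[, 1:3], 1L, sse_at)
  grid <- grid[order(grid$sse, grid$rho), ]
  starts <- utils::head(grid[is.finite(grid$sse), 1:3], n_starts)
  if (nrow(starts) == 0L)
    stop("no finite starting value on the grid; rates may be degenerate",
         call. = FALSE)

  resid_fn <- function(p) {
    r <- rate - lactin_raw(temperature, p[1L], p[2L], p[3L])
    r[!is.finite(r)] <- 1e6
    r
  }
  lower <- c(1e-4, t_hi, 0.05)
  upper <- c(1.5, t_hi + 30, 80)
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    st <- pmin(pmax(as.numeric(starts[k, ]), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 && fit$par[1L] < best$par[1L]))
      best <- list(par = fit$par, sse = sse)
  }
  if (is.null(best))
    stop("Lactin fit failed to converge from all ", nrow(starts),
         " multistart points (grid best SSE ", signif(grid$sse[1L], 4),
         ")", call. = FALSE)

  params <- lactin_params(best$par[1L], best$par[2L], best$par[3L])
  fitted <- lactin_rate(temperature, params)
  res <- rate - fitted
  sst <- sum((rate - mean(rate))^2)
  structure(list(
    params = params,
    coefficients = c(rho = params$rho, t_max = params$t_max,
                     delta_t = params$delta_t),
    fitted.values = fitted,
    residuals = res,
    sse = sum(res^2),
    r.squared = 1 - sum(res^2) / sst,
    data = data.frame(temperature = temperature, rate = rate),
    n_starts = nrow(starts)),
    class = "lactin_fit")
}

#' @export
print.lactin_fit <- function(x, ...) {
  cat("Lactin rate curve fit (", nrow(x$data), " points)\n", sep = "")
  print(round(x$coefficients, 5))
  cat(sprintf("R-squared: %.4f\n", x$r.squared))
  invisible(x)
}

#' @export
coef.lactin_fit <- function(object, ...) object$coefficients

#' @export
fitted.lactin_fit <- function(object, ...) object$fitted.values

#' @export
residuals.lactin_fit <- function(object, ...) object$residuals

#' @export
summary.lactin_fit <- function(object, ...) {
  cat("Lactin temperature-dependent rate model\n")
  cat(sprintf("  n = %d observations, SSE = %.6g, R-squared = %.4f\n",
              nrow(object$data), object$sse, object$r.squared))
  print(round(object$coefficients, 6))
  cat(sprintf("  peak rate %.4f/day; upper limit %.2f degC\n",
              max(lactin_rate(seq(0, object$params$t_max, by = 0.01),
                              object$params)),
              lactin_upper_limit(object$params)))
  invisible(object)
}

#' Predict development rates from a fitted Lactin curve
#'
#' @param object A `"lactin_fit"` object.
#' @param temperature Temperatures (degrees C) at which to predict; if
#'   omitted, the fitted values are returned.
#' @param ... Unused.
#' @return Predicted rates per day (clamped at zero).
#' @export
predict.lactin_fit <- function(object, temperature = NULL, ...) {
  if (is.null(temperature)) return(object$fitted.values)
  lactin_rate(temperature, object$params)
}

#' @export
plot.lactin_fit <- function(x, ...) {
  tt <- seq(min(x$data$temperature) - 2, x$params$t_max + 2, length.out = 300)
  graphics::plot(x$data$temperature, x$data$rate,
                 xlab = "Temperature (degC)", ylab = "Rate (1/day)",
                 main = "Lactin rate curve", ...)
  graphics::lines(tt, lactin_rate(tt, x$params), col = "red3")
  invisible(x)
}
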