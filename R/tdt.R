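#' Thermal death time (TDT) curve parameters
#'
#' A TDT curve describes the log-linear trade-off between exposure
#' temperature and the time an organism (or tissue) tolerates it:
#' tolerated temperature declines by `z` degrees C for every tenfold
#' increase in exposure duration. `ctmax` is the temperature tolerated
#' for exactly the reference duration `t_ref` (1 minute by default).
#'
#' @param ctmax Temperature (degrees C) tolerated for exactly `t_ref` minutes.
#' @param z Thermal sensitivity (degrees C per decade of log10 duration); > 0.
#' @param t_ref Reference duration in minutes; > 0. Default 1.
#'
#' @return An object of class `tdt_params`.
#' @examples
#' pollen <- tdt_params(ctmax = 46, z = 3)
#' failure_time(pollen, 43) # 10 minutes
#' @export
tdt_params <- function(ctmax, z, t_ref = 1) {
  check_finite_scalar(ctmax, "ctmax")
  check_finite_scalar(z, "z")
  check_finite_scalar(t_ref, "t_ref")
  if (z <= 0) stop_tl("`z` must be > 0", "tl_invalid_input")
  if (t_ref <= 0) stop_tl("`t_ref` must be > 0", "tl_invalid_input")
  structure(list(ctmax = ctmax, z = z, t_ref = t_ref), class = "tdt_params")
}

#' @export
print.tdt_params <- function(x, ...) {
  cat(sprintf("TDT curve: ctmax = %.3g degC at t_ref = %g min, z = %.3g degC/decade\n",
              x$ctmax, x$t_ref, x$z))
  invisible(x)
}

is_tdt_params <- function(x) inherits(x, "tdt_params")

check_tdt <- function(params) {
  if (!is_tdt_params(params)) {
    stop_tl("`params` must be a `tdt_params` object", "tl_invalid_input")
  }
  invisible(params)
}

#' Time to failure at a constant exposure temperature
#'
#' Evaluates the TDT curve: `t = t_ref * 10^((ctmax - T) / z)` minutes.
#' Strictly decreasing in temperature.
#'
#' @param params A [tdt_params()] object.
#' @param temperature Exposure temperature(s), degrees C. Must be finite.
#' @return Failure time(s) in minutes.
#' @export
failure_time <- function(params, temperature) {
  check_tdt(params)
  check_finite_vec(temperature, "temperature")
  params$t_ref * 10^((params$ctmax - temperature) / params$z)
}

#' Temperature tolerated for a given exposure duration
#'
#' Exact inverse of [failure_time()]:
#' `T = ctmax - z * log10(duration / t_ref)`.
#'
#' @param params A [tdt_params()] object.
#' @param duration Exposure duration(s) in minutes; > 0.
#' @return Tolerated temperature(s) in degrees C.
#' @export
tolerated_temperature <- function(params, duration) {
  check_tdt(params)
  check_finite_vec(duration, "duration")
  if (any(duration <= 0)) {
    stop_tl("`duration` must be > 0", "tl_invalid_input")
  }
  params$ctmax - params$z * log10(duration / params$t_ref)
}

#' Instantaneous damage accumulation rate
#'
#' The reciprocal of the failure time, in damage fraction per minute:
#' constant exposure at temperature T for `failure_time(T)` minutes
#' accumulates exactly total damage 1.
#'
#' @inheritParams failure_time
#' @return Damage rate(s), fraction per minute; strictly increasing in T.
#' @export
damage_rate <- function(params, temperature) {
  1 / failure_time(params, temperature)
}

#' Static heat-tolerance assay records
#'
#' Container for (exposure temperature, time to failure) observations from
#' static assays, the empirical input of [fit_tdt()]. Optionally carries an
#' individual/stage label per record.
#'
#' @param temperature Exposure temperatures, degrees C.
#' @param failure_time Observed times to failure, minutes; all > 0.
#' @param id Optional per-record labels (individual or replicate).
#' @param stage Optional single stage label.
#' @return A `data.frame` with class `tdt_assay`.
#' @export
tdt_assay <- function(temperature, failure_time, id = NULL, stage = NULL) {
  check_finite_vec(temperature, "temperature")
  check_finite_vec(failure_time, "failure_time")
  if (length(temperature) != length(failure_time)) {
    stop_tl("`temperature` and `failure_time` must have equal length",
            "tl_invalid_input")
  }
  if (any(failure_time <= 0)) {
    stop_tl("all `failure_time` values must be > 0", "tl_invalid_input")
  }
  d <- data.frame(temperature = temperature, failure_time = failure_time)
  if (!is.null(id)) d$id <- rep_len(id, nrow(d))
  attr(d, "stage") <- stage
  class(d) <- c("tdt_assay", "data.frame")
  d
}

#' Fit a TDT curve to static assay data
#'
#' Ordinary least squares of `log10(failure_time / t_ref)` on temperature
#' (failure time is the measured response, hence regressed on temperature).
#' Slope `b` and intercept `a` convert to `z = -1/b` and `ctmax = -a/b`;
#' standard errors follow by the delta method from the regression
#' variance-covariance matrix.
#'
#' @param assay A [tdt_assay()] or a data.frame with columns `temperature`
#'   and `failure_time`.
#' @param t_ref Reference duration (minutes) of the fitted parameterization.
#' @return An object of class `tdt_fit` with elements `params`
#'   ([tdt_params()]), `se_ctmax`, `se_z`, `sigma` (residual sd in log10
#'   minutes) and `n_obs`.
#' @examples
#' a <- tdt_assay(c(40, 43, 46), c(100, 10, 1))
#' fit_tdt(a)$params
#' @export
fit_tdt <- function(assay, t_ref = 1) {
  if (!is.data.frame(assay) ||
      !all(c("temperature", "failure_time") %in% names(assay))) {
    stop_tl("`assay` must have columns `temperature` and `failure_time`",
            "tl_invalid_input")
  }
  temp <- assay$temperature
  ft <- assay$failure_time
  check_finite_vec(temp, "temperature")
  check_finite_vec(ft, "failure_time")
  if (any(ft <= 0)) stop_tl("all failure times must be > 0", "tl_invalid_input")
  if (length(unique(temp)) < 2L) {
    stop_tl("fitting requires at least 2 distinct exposure temperatures",
            "tl_degenerate_design")
  }
  y <- log10(ft / t_ref)
  fit <- stats::lm(y ~ temp)
  a <- unname(stats::coef(fit)[1L])
  b <- unname(stats::coef(fit)[2L])
  if (!is.finite(b) || b >= 0) {
    stop_tl(sprintf(
      "fitted slope (%.4g) is not negative: data do not show TDT behaviour (failure time must decline with temperature)",
      b), "tl_non_tdt")
  }
  V <- stats::vcov(fit)
  ## z = -1/b ; ctmax = -a/b ; delta-method gradients
  var_z <- V[2L, 2L] / b^4
  g <- c(-1 / b, a / b^2)
  var_ctmax <- drop(t(g) %*% V %*% g)
  s <- summary(fit)$sigma
  structure(list(
    params = tdt_params(ctmax = -a / b, z = -1 / b, t_ref = t_ref),
    se_ctmax = sqrt(max(var_ctmax, 0)),
    se_z = sqrt(max(var_z, 0)),
    sigma = if (is.finite(s)) s else 0,
    n_obs = length(y)
  ), class = "tdt_fit")
}

#' @export
print.tdt_fit <- function(x, ...) {
  cat(sprintf(
    "TDT fit (n = %d): ctmax = %.2f +/- %.3f degC, z = %.3f +/- %.3f degC/decade, residual sd = %.3f log10-min\n",
    x$n_obs, x$params$ctmax, x$se_ctmax, x$params$z, x$se_z, x$sigma))
  invisible(x)
}
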