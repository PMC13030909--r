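#' Temperature-dependent repair-rate parameters
#'
#' Repair of accumulated heat injury is modelled as a temperature-dependent
#' rate (damage fraction per minute). Three shapes are supported:
#'
#' * `"arrhenius"` (default): `r(T) = r_ref * exp[(e_a / k_B) *
#'   (1/T_ref_K - 1/T_K)]` with temperatures in Kelvin and
#'   `k_B = 8.617e-5` eV/K. Repair accelerates with temperature, as for
#'   an enzymatic process with activation energy `e_a` (eV).
#' * `"gaussian"`: `r(T) = r_ref * exp[-0.5 * ((T - t_opt)/sigma)^2]`, a
#'   peaked alternative for repair machinery with a thermal optimum.
#' * `"off"`: repair disabled, rate identically zero.
#'
#' @param shape One of `"arrhenius"`, `"gaussian"`, `"off"`.
#' @param r_ref Repair rate (fraction/minute) at the reference temperature
#'   (`t_ref_repair` for arrhenius, `t_opt` for gaussian); >= 0.
#' @param e_a Activation energy in eV (arrhenius shape). Default 0.65.
#' @param t_ref_repair Reference temperature, degrees C (arrhenius shape).
#' @param t_opt Peak temperature, degrees C (gaussian shape).
#' @param sigma Breadth, degrees C (gaussian shape); > 0.
#' @return An object of class `repair_params`.
#' @export
repair_params <- function(shape = c("arrhenius", "gaussian", "off"),
                          r_ref = 0, e_a = 0.65, t_ref_repair = 25,
                          t_opt = NULL, sigma = NULL) {
  shape <- match.arg(shape)
  if (shape != "off") {
    check_finite_scalar(r_ref, "r_ref")
    if (r_ref < 0) stop_tl("`r_ref` must be >= 0", "tl_invalid_input")
  }
  if (shape == "arrhenius") {
    check_finite_scalar(e_a, "e_a")
    check_finite_scalar(t_ref_repair, "t_ref_repair")
  }
  if (shape == "gaussian") {
    check_finite_scalar(t_opt, "t_opt")
    check_finite_scalar(sigma, "sigma")
    if (sigma <= 0) stop_tl("`sigma` must be > 0", "tl_invalid_input")
  }
  structure(list(shape = shape, r_ref = if (shape == "off") 0 else r_ref,
                 e_a = e_a, t_ref_repair = t_ref_repair,
                 t_opt = t_opt, sigma = sigma),
            class = "repair_params")
}

#' @export
print.repair_params <- function(x, ...) {
  switch(x$shape,
    off = cat("Repair: off\n"),
    arrhenius = cat(sprintf(
      "Repair: Arrhenius, r_ref = %.4g /min at %.3g degC, e_a = %.3g eV\n",
      x$r_ref, x$t_ref_repair, x$e_a)),
    gaussian = cat(sprintf(
      "Repair: Gaussian, r_ref = %.4g /min at t_opt = %.3g degC, sigma = %.3g degC\n",
      x$r_ref, x$t_opt, x$sigma)))
  invisible(x)
}

check_repair <- function(repair) {
  if (!inherits(repair, "repair_params")) {
    stop_tl("`repair` must be a `repair_params` object", "tl_invalid_input")
  }
  invisible(repair)
}

#' Repair rate at a given temperature
#'
#' @param repair A [repair_params()] object.
#' @param temperature Temperature(s), degrees C; finite.
#' @return Repair rate(s), damage fraction per minute (always >= 0).
#' @export
repair_rate <- function(repair, temperature) {
  check_repair(repair)
  check_finite_vec(temperature, "temperature")
  switch(repair$shape,
    off = rep(0, length(temperature)),
    arrhenius = repair$r_ref * exp((repair$e_a / .k_B) *
      (1 / (repair$t_ref_repair + .T0K) - 1 / (temperature + .T0K))),
    gaussian = repair$r_ref *
      exp(-0.5 * ((temperature - repair$t_opt) / repair$sigma)^2))
}

#' Calibrate a repair function to a damage/repair crossover temperature
#'
#' Scales `r_ref` so that the repair rate equals the TDT damage rate
#' exactly at the crossover temperature `t_cross`, and anchors the shape's
#' reference temperature there. Below `t_cross` repair then outweighs
#' damage (the permissive range); above it damage dominates (the
#' stressful range).
#'
#' @param tdt A [tdt_params()] object.
#' @param t_cross Crossover temperature, degrees C.
#' @param shape `"arrhenius"` (default) or `"gaussian"`.
#' @param e_a Activation energy, eV (arrhenius).
#' @param sigma Breadth, degrees C (gaussian). Default 5.
#' @return A calibrated [repair_params()] object with
#'   `repair_rate(t_cross) == damage_rate(tdt, t_cross)`.
#' @examples
#' calibrate_repair(tdt_params(46, 3), t_cross = 31)  # r_ref = 1e-5 /min
#' @export
calibrate_repair <- function(tdt, t_cross, shape = c("arrhenius", "gaussian"),
                             e_a = 0.65, sigma = 5) {
  check_tdt(tdt)
  check_finite_scalar(t_cross, "t_cross")
  shape <- tryCatch(match.arg(shape), error = function(e) {
    stop_tl("repair calibration is undefined for shape `off`",
            "tl_invalid_input")
  })
  r0 <- damage_rate(tdt, t_cross)
  if (shape == "arrhenius") {
    repair_params("arrhenius", r_ref = r0, e_a = e_a, t_ref_repair = t_cross)
  } else {
    repair_params("gaussian", r_ref = r0, t_opt = t_cross, sigma = sigma)
  }
}

#' Net damage rate (damage minus repair)
#'
#' Negative in the permissive range (net repair), positive in the
#' stressful range where damage accumulates exponentially with
#' temperature.
#'
#' @param tdt A [tdt_params()] object.
#' @param repair A [repair_params()] object.
#' @param temperature Temperature(s), degrees C.
#' @return Signed net rate(s), fraction per minute.
#' @export
net_damage_rate <- function(tdt, repair, temperature) {
  damage_rate(tdt, temperature) - repair_rate(repair, temperature)
}

#' Permissive/stressful boundary temperature
#'
#' Locates the temperature at which the net damage rate crosses zero by
#' bisection. With an Arrhenius repair slope well below the damage slope
#' `ln(10)/z`, the crossover on a sensible bracket is unique.
#'
#' @param tdt A [tdt_params()] object.
#' @param repair A [repair_params()] object.
#' @param bracket Length-2 numeric bracket, degrees C. Default `c(0, 60)`.
#' @param tol Bisection tolerance, degrees C. Default `1e-6`.
#' @return The crossover temperature, degrees C.
#' @export
permissive_boundary <- function(tdt, repair, bracket = c(0, 60), tol = 1e-6) {
  check_tdt(tdt)
  check_repair(repair)
  check_finite_vec(bracket, "bracket")
  if (length(bracket) != 2L || bracket[1L] >= bracket[2L]) {
    stop_tl("`bracket` must be an increasing pair of temperatures",
            "tl_invalid_input")
  }
  lo <- bracket[1L]; hi <- bracket[2L]
  f_lo <- net_damage_rate(tdt, repair, lo)
  f_hi <- net_damage_rate(tdt, repair, hi)
  if (f_lo == 0) return(lo)
  if (f_hi == 0) return(hi)
  if (sign(f_lo) == sign(f_hi)) {
    stop_tl(sprintf(
      "net damage rate does not change sign on [%g, %g] degC (no permissive/stressful crossover; is repair off?)",
      lo, hi), "tl_no_crossover")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- net_damage_rate(tdt, repair, mid)
    if (f_mid == 0) return(mid)
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}
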