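#' Synthetic weather scenario
#'
#' Generative description of a multi-day weather experiment: a smooth
#' diurnal air-temperature cycle at 1.2 m between daily `tmin` (at
#' sunrise) and `tmax` (mid-afternoon), optional heatwave days that boost
#' `tmax`, and rain days that zero the solar proxy, cool the day and
#' reset soil dryness. Stands in for an external biophysical microclimate
#' model so that every pipeline input has known ground truth.
#'
#' @param n_days Number of simulated days; >= 1.
#' @param tmin,tmax Daily minimum / maximum air temperature, degrees C;
#'   scalars or length-`n_days` vectors. Defaults 18 / 30.
#' @param heatwave_days Integer day indices (1-based) whose `tmax` is
#'   raised by `tmax_boost`.
#' @param tmax_boost Heatwave boost, degrees C. Default 12.
#' @param rain_days Integer day indices with rainfall: solar proxy 0 all
#'   day, dryness 0, `tmax` lowered by `rain_cool`.
#' @param rain_cool Cooling of `tmax` on rain days, degrees C. Default 6.
#' @param daylength_hours Hours of daylight, in (0, 24). Default 14
#'   (austral summer).
#' @param dryness_recovery_days Days for soil dryness to relax linearly
#'   back to 1 after rain. Default 3.
#' @param tmax_jitter_sd Optional sd (degrees C) of a per-day Gaussian
#'   jitter on `tmax` (0 disables; the default).
#' @param start Calendar date of day 1 (UTC). Default "2020-01-01".
#' @param seed RNG seed used when `tmax_jitter_sd > 0`.
#' @return An object of class `weather_scenario`.
#' @export
weather_scenario <- function(n_days, tmin = 18, tmax = 30,
                             heatwave_days = integer(), tmax_boost = 12,
                             rain_days = integer(), rain_cool = 6,
                             daylength_hours = 14,
                             dryness_recovery_days = 3,
                             tmax_jitter_sd = 0,
                             start = "2020-01-01", seed = 1L) {
  check_finite_scalar(n_days, "n_days")
  if (n_days < 1 || n_days != round(n_days)) {
    stop_tl("`n_days` must be a positive integer", "tl_config_error")
  }
  check_finite_scalar(daylength_hours, "daylength_hours")
  if (daylength_hours <= 0 || daylength_hours >= 24) {
    stop_tl("`daylength_hours` must lie in (0, 24)", "tl_config_error")
  }
  check_finite_scalar(dryness_recovery_days, "dryness_recovery_days")
  if (dryness_recovery_days <= 0) {
    stop_tl("`dryness_recovery_days` must be > 0", "tl_config_error")
  }
  check_finite_scalar(tmax_boost, "tmax_boost")
  check_finite_scalar(rain_cool, "rain_cool")
  check_finite_scalar(tmax_jitter_sd, "tmax_jitter_sd")
  if (tmax_jitter_sd < 0) {
    stop_tl("`tmax_jitter_sd` must be >= 0", "tl_config_error")
  }
  tmin <- rep_len(as.numeric(tmin), n_days)
  tmax <- rep_len(as.numeric(tmax), n_days)
  check_finite_vec(tmin, "tmin"); check_finite_vec(tmax, "tmax")
  for (d in list(heatwave = heatwave_days, rain = rain_days)) {
    if (length(d) && (any(d != round(d)) || any(d < 1) || any(d > n_days))) {
      stop_tl("day indices must be integers in [1, n_days]", "tl_config_error")
    }
  }
  hw <- seq_len(n_days) %in% heatwave_days
  rn <- seq_len(n_days) %in% rain_days
  tmax_eff <- tmax + ifelse(hw, tmax_boost, 0) - ifelse(rn, rain_cool, 0)
  if (any(tmax_eff < tmin)) {
    stop_tl("effective tmax (after heatwave boost / rain cooling) must be >= tmin on every day",
            "tl_config_error")
  }
  structure(list(
    n_days = as.integer(n_days), tmin = tmin, tmax = tmax,
    heatwave_days = as.integer(heatwave_days), tmax_boost = tmax_boost,
    rain_days = as.integer(rain_days), rain_cool = rain_cool,
    daylength_hours = daylength_hours,
    dryness_recovery_days = dryness_recovery_days,
    tmax_jitter_sd = tmax_jitter_sd,
    start = as.character(start), seed = as.integer(seed)
  ), class = "weather_scenario")
}

#' @export
print.weather_scenario <- function(x, ...) {
  cat(sprintf(
    "Weather scenario: %d days from %s, tmin %s / tmax %s degC\n  heatwave days: %s (+%g degC); rain days: %s\n",
    x$n_days, x$start,
    paste(range(x$tmin), collapse = "-"), paste(range(x$tmax), collapse = "-"),
    if (length(x$heatwave_days)) paste(x$heatwave_days, collapse = ",") else "none",
    x$tmax_boost,
    if (length(x$rain_days)) paste(x$rain_days, collapse = ",") else "none"))
  invisible(x)
}

#' Read / write a weather scenario as YAML
#'
#' @param path YAML file path.
#' @return `read_scenario_yaml()` returns a [weather_scenario()];
#'   `write_scenario_yaml()` returns `path` invisibly.
#' @export
read_scenario_yaml <- function(path) {
  if (!file.exists(path)) {
    stop_tl(sprintf("scenario file not found: %s", path), "tl_config_error")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(weather_scenario))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop_tl(sprintf("unknown scenario field(s): %s",
                    paste(extra, collapse = ", ")), "tl_config_error")
  }
  do.call(weather_scenario, raw)
}

#' @rdname read_scenario_yaml
#' @param scenario A [weather_scenario()] object.
#' @export
write_scenario_yaml <- function(scenario, path) {
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

## Day-shape anchors in hours: sunrise/sunset around solar noon, with the
## temperature and solar peak at 5/7 of the daylength after sunrise
## (15:00 for the default 14 h daylength, i.e. mid-afternoon).
.day_anchors <- function(daylength_hours) {
  sunrise <- 12 - daylength_hours / 2
  sunset <- 12 + daylength_hours / 2
  list(sunrise = sunrise, sunset = sunset,
       peak = sunrise + daylength_hours * 5 / 7)
}

#' Generate a synthetic 1.2 m air-temperature series
#'
#' Air temperature follows, per day, a rising half-sinusoid from `tmin`
#' at sunrise to the day's effective `tmax` mid-afternoon, a falling
#' quarter-cosine back to `tmin` at sunset, and linear interpolation
#' overnight towards the next day's `tmin`. The solar proxy is a skewed
#' half-sine over daylight peaking (value 1) at the same mid-afternoon
#' instant as the temperature — so surface-excess maxima compose exactly
#' — and is 0 at night and on rain days. Soil dryness is 1, drops to 0
#' on rain days and relaxes linearly back to 1 over
#' `dryness_recovery_days`. Deterministic given the scenario seed.
#'
#' @param scenario A [weather_scenario()] object.
#' @param step_minutes Sampling step in minutes; must divide 1440.
#'   Default 10.
#' @return A `microclim` series at height 120 cm with solar, dryness and
#'   rain traces.
#' @export
generate_weather <- function(scenario, step_minutes = 10) {
  if (!inherits(scenario, "weather_scenario")) {
    stop_tl("`scenario` must be a `weather_scenario` object", "tl_config_error")
  }
  check_finite_scalar(step_minutes, "step_minutes")
  if (step_minutes <= 0 || 1440 %% step_minutes != 0) {
    stop_tl("`step_minutes` must be a positive divisor of 1440",
            "tl_config_error")
  }
  nd <- scenario$n_days
  hw <- seq_len(nd) %in% scenario$heatwave_days
  rn <- seq_len(nd) %in% scenario$rain_days
  tmin <- scenario$tmin
  tmax <- scenario$tmax + ifelse(hw, scenario$tmax_boost, 0) -
    ifelse(rn, scenario$rain_cool, 0)
  if (scenario$tmax_jitter_sd > 0) {
    jitter <- with_seed(scenario$seed,
                        stats::rnorm(nd, 0, scenario$tmax_jitter_sd))
    tmax <- pmax(tmin + 0.1, tmax + jitter)
  }
  anc <- .day_anchors(scenario$daylength_hours)

  t_min <- seq(0, nd * 1440, by = step_minutes)     # minutes since midnight d1
  t_hr <- t_min / 60
  day <- pmin(floor(t_hr / 24) + 1, nd)             # final midnight -> last day
  h <- t_hr - (day - 1) * 24                        # hour of day
  h[t_min == nd * 1440] <- 24                       # closing midnight

  tmin_d <- tmin[day]
  tmax_d <- tmax[day]
  tmin_prev <- tmin[pmax(day - 1, 1)]
  tmin_next <- tmin[pmin(day + 1, nd)]

  night_len <- 24 - anc$sunset + anc$sunrise
  temp <- numeric(length(h))
  pre <- h < anc$sunrise
  rise <- h >= anc$sunrise & h <= anc$peak
  fall <- h > anc$peak & h <= anc$sunset
  post <- h > anc$sunset
  ## pre-dawn: tail of last night's linear cooling (previous tmin -> today's)
  frac_pre <- (h[pre] + 24 - anc$sunset) / night_len
  temp[pre] <- tmin_prev[pre] + (tmin_d[pre] - tmin_prev[pre]) * frac_pre
  temp[rise] <- tmin_d[rise] + (tmax_d[rise] - tmin_d[rise]) *
    sin(pi / 2 * (h[rise] - anc$sunrise) / (anc$peak - anc$sunrise))
  temp[fall] <- tmin_d[fall] + (tmax_d[fall] - tmin_d[fall]) *
    cos(pi / 2 * (h[fall] - anc$peak) / (anc$sunset - anc$peak))
  frac_post <- (h[post] - anc$sunset) / night_len
  temp[post] <- tmin_d[post] + (tmin_next[post] - tmin_d[post]) * frac_post

  ## solar proxy: skewed half-sine peaking with the temperature
  solar <- numeric(length(h))
  s_rise <- rise
  solar[s_rise] <- sin(pi / 2 * (h[s_rise] - anc$sunrise) /
                         (anc$peak - anc$sunrise))
  solar[fall] <- sin(pi / 2 *
                       (1 - (h[fall] - anc$peak) / (anc$sunset - anc$peak)))
  solar[rn[day]] <- 0
  solar <- pmin(pmax(solar, 0), 1)

  ## dryness: 0 on rain days, linear recovery afterwards
  rain_day_end <- rep(-Inf, length(h))
  rain_idx <- which(rn)
  t_days <- t_min / 1440
  if (length(rain_idx)) {
    last_rain_end <- vapply(t_days, function(td) {
      past <- rain_idx[rain_idx <= ceiling(td + 1e-12)]
      ## a rain day d spans [d-1, d] in day units
      past <- past[past - 1 <= td]
      if (length(past)) max(past) else -Inf
    }, numeric(1))
    rain_day_end <- last_rain_end
  }
  in_rain <- rn[day]
  since <- t_days - rain_day_end
  dryness <- pmin(1, pmax(0, since / scenario$dryness_recovery_days))
  dryness[in_rain] <- 0
  dryness[!is.finite(rain_day_end)] <- 1
  dryness[in_rain] <- 0

  time <- as.POSIXct(scenario$start, tz = "UTC") + t_min * 60
  microclim(time, matrix(temp, ncol = 1), 120,
            solar = solar, dryness = dryness, rain = in_rain)
}

#' Generate a height-stratified synthetic microclimate series
#'
#' Composition of [generate_weather()] and [apply_profile()]: on a dry,
#' clear day with the default profile and zero shade, the surface (0 cm)
#' daily maximum exceeds the air maximum by `a0` (20 degC) and the 1 cm
#' maximum by 8 degC.
#'
#' @inheritParams generate_weather
#' @param profile A [profile_params()] object.
#' @param heights Heights (cm) to simulate. Default `c(0, 1, 50)`.
#' @return A `microclim` series at `heights` plus the 120 cm reference.
#' @export
generate_microclimate <- function(scenario, profile = profile_params(),
                                  heights = c(0, 1, 50), step_minutes = 10) {
  air <- generate_weather(scenario, step_minutes)
  apply_profile(air, profile, heights)
}

#' Generate a synthetic static heat-tolerance assay
#'
#' Draws failure times log-normally around the true TDT line:
#' `t_obs = 10^(log10(failure_time(T)) + e)`, `e ~ N(0, noise_sd)`, the
#' noise model matching the regression model of [fit_tdt()] so that
#' parameter-recovery experiments are well posed.
#'
#' @param true_params A [tdt_params()] object (ground truth).
#' @param temperatures Assay temperatures, degrees C; non-empty.
#' @param reps_per_temp Replicates per temperature; >= 1. Default 10.
#' @param noise_sd Log10-minutes noise sd; >= 0. Default 0.1.
#' @param seed RNG seed (deterministic output).
#' @return A [tdt_assay()] with `reps_per_temp * length(temperatures)` rows.
#' @export
generate_tdt_assay <- function(true_params, temperatures, reps_per_temp = 10,
                               noise_sd = 0.1, seed = 1L) {
  check_tdt(true_params)
  if (length(temperatures) == 0L) {
    stop_tl("`temperatures` must be non-empty", "tl_invalid_input")
  }
  check_finite_vec(temperatures, "temperatures")
  check_finite_scalar(reps_per_temp, "reps_per_temp")
  check_finite_scalar(noise_sd, "noise_sd")
  if (reps_per_temp < 1) stop_tl("`reps_per_temp` must be >= 1", "tl_invalid_input")
  if (noise_sd < 0) stop_tl("`noise_sd` must be >= 0", "tl_invalid_input")
  temp <- rep(temperatures, each = reps_per_temp)
  eps <- with_seed(seed, stats::rnorm(length(temp), 0, noise_sd))
  ft <- 10^(log10(failure_time(true_params, temp)) + eps)
  tdt_assay(temp, ft, id = rep(seq_len(reps_per_temp), times = length(temperatures)))
}
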