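#' Height-stratified microclimate temperature series
#'
#' Container for uniformly sampled temperature trajectories at one or more
#' heights above the soil surface, with optional per-time solar proxy
#' (dimensionless, in `[0, 1]`), soil dryness (`[0, 1]`) and rainfall flag.
#' The 1.2 m (120 cm) trace is the standard air-temperature reference from
#' which near-ground traces are derived via [apply_profile()].
#'
#' @param time `POSIXct` timestamps, strictly increasing with a uniform
#'   step (minutes resolution).
#' @param temp Numeric matrix, one row per timestamp, one column per
#'   height.
#' @param heights Heights above soil in cm (>= 0), one per column of
#'   `temp`.
#' @param solar Optional solar proxy vector in `[0, 1]`.
#' @param dryness Optional soil dryness vector in `[0, 1]` (1 = fully dry).
#' @param rain Optional logical rainfall flag vector.
#' @return An object of class `microclim`.
#' @export
microclim <- function(time, temp, heights, solar = NULL, dryness = NULL,
                      rain = NULL) {
  if (!inherits(time, "POSIXct")) {
    stop_tl("`time` must be POSIXct", "tl_invalid_input")
  }
  n <- length(time)
  if (n < 2L) stop_tl("series needs at least 2 timestamps", "tl_invalid_input")
  dt <- diff(as.numeric(time))
  if (any(dt <= 0)) {
    stop_tl("timestamps must be strictly increasing", "tl_invalid_input")
  }
  if (max(dt) - min(dt) > 1e-6) {
    stop_tl("timestamps must be uniformly spaced", "tl_invalid_input")
  }
  temp <- as.matrix(temp)
  if (nrow(temp) != n) {
    stop_tl("`temp` must have one row per timestamp", "tl_invalid_input")
  }
  check_finite_vec(heights, "heights")
  if (length(heights) != ncol(temp)) {
    stop_tl("`heights` must match the columns of `temp`", "tl_invalid_input")
  }
  if (any(heights < 0)) stop_tl("heights must be >= 0", "tl_invalid_input")
  if (anyDuplicated(heights)) {
    stop_tl("heights must be unique", "tl_invalid_input")
  }
  for (v in list(solar = solar, dryness = dryness)) if (!is.null(v)) {
    if (length(v) != n || any(!is.finite(v)) || any(v < -1e-12 | v > 1 + 1e-12)) {
      stop_tl("solar/dryness traces must lie in [0, 1] and match the series length",
              "tl_invalid_input")
    }
  }
  if (!is.null(rain) && length(rain) != n) {
    stop_tl("`rain` must match the series length", "tl_invalid_input")
  }
  colnames(temp) <- format(heights, trim = TRUE)
  structure(list(time = time, temp = temp, heights = as.numeric(heights),
                 solar = solar, dryness = dryness,
                 rain = if (is.null(rain)) NULL else as.logical(rain)),
            class = "microclim")
}

#' @export
print.microclim <- function(x, ...) {
  cat(sprintf(
    "Microclimate series: %d steps of %g min, %s to %s\n  heights (cm): %s\n  extras: %s\n",
    length(x$time), mc_step_minutes(x),
    format(x$time[1L], "%Y-%m-%d %H:%M"),
    format(x$time[length(x$time)], "%Y-%m-%d %H:%M"),
    paste(x$heights, collapse = ", "),
    paste(c("solar", "dryness", "rain")[
      !vapply(list(x$solar, x$dryness, x$rain), is.null, logical(1))],
      collapse = ", ")))
  invisible(x)
}

#' @rdname microclim
#' @param x A `microclim` object.
#' @export
mc_heights <- function(x) x$heights

#' @rdname microclim
#' @export
mc_step_minutes <- function(x) as.numeric(diff(as.numeric(x$time[1:2]))) / 60

#' Extract the temperature trace at one height
#' @param x A `microclim` object.
#' @param height Height in cm; must be present in the series.
#' @return Numeric temperature vector.
#' @export
mc_trace <- function(x, height) {
  i <- match(height, x$heights)
  if (is.na(i)) {
    stop_tl(sprintf("height %g cm not present in series (available: %s)",
                    height, paste(x$heights, collapse = ", ")),
            "tl_config_error")
  }
  x$temp[, i]
}

#' Shift all temperature traces by a constant (degrees C)
#' @param x A `microclim` object.
#' @param delta Temperature offset in degrees C.
#' @export
mc_shift <- function(x, delta) {
  check_finite_scalar(delta, "delta")
  x$temp <- x$temp + delta
  x
}

#' Vertical temperature-excess profile parameters
#'
#' A deliberately simple surrogate for a full soil energy-balance model:
#' under solar load, dry bare soil heats far above air temperature, and
#' the excess decays exponentially with height. Defaults are calibrated
#' to a clear-sky, dry-soil peak excess of +20 degC at the surface and
#' +8 degC at 1 cm (hence `h_scale = 1/ln(20/8) = 1/ln(2.5)` cm). At
#' night the surface radiatively cools slightly below air temperature.
#'
#' @param a0 Maximum clear-sky dry-soil surface excess, degrees C; >= 0.
#'   Default 20.
#' @param h_scale Exponential decay length of the excess with height, cm;
#'   > 0. Default `1/log(2.5)` (about 1.0914).
#' @param night_deficit Nocturnal surface cooling amplitude, degrees C;
#'   >= 0. Default 2.
#' @param shade_fraction Fractional shading in `[0, shade_max]`; scales
#'   the daytime excess by `1 - shade_fraction`. Default 0.
#' @param shade_max Upper bound for `shade_fraction` (thin-canopy
#'   assumption). Default 0.6.
#' @return An object of class `profile_params`.
#' @export
profile_params <- function(a0 = 20, h_scale = 1 / log(2.5), night_deficit = 2,
                           shade_fraction = 0, shade_max = 0.6) {
  check_finite_scalar(a0, "a0")
  check_finite_scalar(h_scale, "h_scale")
  check_finite_scalar(night_deficit, "night_deficit")
  check_finite_scalar(shade_fraction, "shade_fraction")
  if (a0 < 0) stop_tl("`a0` must be >= 0", "tl_invalid_input")
  if (h_scale <= 0) stop_tl("`h_scale` must be > 0", "tl_invalid_input")
  if (night_deficit < 0) stop_tl("`night_deficit` must be >= 0", "tl_invalid_input")
  if (shade_fraction < 0 || shade_fraction > shade_max) {
    stop_tl(sprintf("`shade_fraction` must lie in [0, %g]", shade_max),
            "tl_invalid_input")
  }
  structure(list(a0 = a0, h_scale = h_scale, night_deficit = night_deficit,
                 shade_fraction = shade_fraction, shade_max = shade_max),
            class = "profile_params")
}

#' Temperature excess over air temperature at a given height
#'
#' Daytime (`solar > 0`):
#' `a0 * solar * dryness * (1 - shade_fraction) * exp(-height / h_scale)`.
#' Night (`solar == 0`): `-night_deficit * exp(-height / h_scale)`.
#'
#' @param profile A [profile_params()] object.
#' @param height Height above soil, cm; >= 0.
#' @param solar Solar proxy in `[0, 1]` (vectorised).
#' @param dryness Soil dryness in `[0, 1]` (vectorised).
#' @return Temperature excess(es), degrees C.
#' @examples
#' p <- profile_params()
#' vertical_offset(p, 0, 1, 1)  # +20
#' vertical_offset(p, 1, 1, 1)  # +8
#' @export
vertical_offset <- function(profile, height, solar, dryness) {
  if (!inherits(profile, "profile_params")) {
    stop_tl("`profile` must be a `profile_params` object", "tl_invalid_input")
  }
  check_finite_scalar(height, "height")
  if (height < 0) stop_tl("`height` must be >= 0", "tl_invalid_input")
  check_finite_vec(solar, "solar")
  check_finite_vec(dryness, "dryness")
  if (any(solar < 0 | solar > 1)) {
    stop_tl("`solar` must lie in [0, 1]", "tl_invalid_input")
  }
  if (any(dryness < 0 | dryness > 1)) {
    stop_tl("`dryness` must lie in [0, 1]", "tl_invalid_input")
  }
  decay <- exp(-height / profile$h_scale)
  ifelse(solar > 0,
         profile$a0 * solar * dryness * (1 - profile$shade_fraction) * decay,
         -profile$night_deficit * decay)
}

#' Derive near-ground traces from an air-temperature series
#'
#' Adds one temperature trace per requested height:
#' `T(h, t) = T_air(t) + vertical_offset(h, solar(t), dryness(t))`, where
#' `T_air` is the 120 cm (1.2 m) reference trace. The air trace itself is
#' preserved unchanged in the output.
#'
#' @param air A `microclim` series containing a 120 cm trace plus `solar`
#'   and `dryness` traces.
#' @param profile A [profile_params()] object.
#' @param heights Heights (cm) to derive.
#' @return A `microclim` series with the derived traces and the original
#'   air reference.
#' @export
apply_profile <- function(air, profile, heights = c(0, 1, 50)) {
  if (!inherits(air, "microclim")) {
    stop_tl("`air` must be a `microclim` object", "tl_invalid_input")
  }
  if (!(120 %in% air$heights)) {
    stop_tl("`air` must contain the 120 cm reference trace", "tl_config_error")
  }
  if (is.null(air$solar) || is.null(air$dryness)) {
    stop_tl("`air` must carry solar and dryness traces to derive a profile",
            "tl_config_error")
  }
  check_finite_vec(heights, "heights")
  t_air <- mc_trace(air, 120)
  hs <- sort(unique(c(heights, 120)))
  temp <- vapply(hs, function(h) {
    if (h == 120) t_air
    else t_air + vertical_offset(profile, h, air$solar, air$dryness)
  }, numeric(length(t_air)))
  microclim(air$time, temp, hs, solar = air$solar, dryness = air$dryness,
            rain = air$rain)
}

.mc_time_fmt <- "%Y-%m-%dT%H:%M:%S"

#' Write a microclimate series to CSV
#'
#' Long format, one row per (height, timestamp), sorted by height then
#' time. Columns: `datetime` (ISO 8601, UTC), `height_cm`, `temp_C`, and
#' (when present) `solar`, `dryness`, `rain`. Numeric values carry 9
#' decimal places so the round trip is lossless to well below measurement
#' precision.
#'
#' @param series A `microclim` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_microclimate_csv <- function(series, path) {
  if (!inherits(series, "microclim")) {
    stop_tl("`series` must be a `microclim` object", "tl_invalid_input")
  }
  n <- length(series$time)
  rows <- lapply(seq_along(series$heights), function(i) {
    d <- data.frame(
      datetime = format(series$time, .mc_time_fmt, tz = "UTC"),
      height_cm = format(series$heights[i], trim = TRUE),
      temp_C = sprintf("%.9f", series$temp[, i]))
    if (!is.null(series$solar)) d$solar <- sprintf("%.9f", series$solar)
    if (!is.null(series$dryness)) d$dryness <- sprintf("%.9f", series$dryness)
    if (!is.null(series$rain)) d$rain <- as.integer(series$rain)
    d
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a microclimate series from CSV
#'
#' Expects the format written by [write_microclimate_csv()] (also the
#' natural export format of external microclimate models): columns
#' `datetime` (ISO 8601), `height_cm`, `temp_C`, optional `solar`,
#' `dryness`, `rain`. Validation errors report offending row numbers.
#'
#' @param path CSV file path.
#' @param strict If `TRUE` (default) rows out of (height, time) order are
#'   rejected; if `FALSE` they are re-sorted deterministically.
#' @return A `microclim` object.
#' @export
read_microclimate_csv <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    stop_tl(sprintf("file not found: %s", path), "tl_format_error")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("datetime", "height_cm", "temp_C")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop_tl(sprintf("microclimate CSV is missing column(s): %s",
                    paste(missing, collapse = ", ")), "tl_format_error")
  }
  tm <- as.POSIXct(d$datetime, format = .mc_time_fmt, tz = "UTC")
  bad <- which(is.na(tm))
  if (length(bad)) {
    stop_tl(sprintf("unparseable datetime at row(s): %s",
                    paste(utils::head(bad, 5L), collapse = ", ")),
            "tl_format_error")
  }
  bad <- which(!is.finite(d$temp_C))
  if (length(bad)) {
    stop_tl(sprintf("non-numeric temp_C at row(s): %s",
                    paste(utils::head(bad, 5L), collapse = ", ")),
            "tl_format_error")
  }
  ord <- order(d$height_cm, as.numeric(tm))
  if (is.unsorted(ord) || any(ord != seq_along(ord))) {
    if (strict) {
      first_bad <- which(ord != seq_along(ord))[1L]
      stop_tl(sprintf(
        "rows are not sorted by (height_cm, datetime); first offending row: %d (use strict = FALSE to re-sort)",
        first_bad), "tl_format_error")
    }
    d <- d[ord, , drop = FALSE]
    tm <- tm[ord]
  }
  hs <- sort(unique(d$height_cm))
  per_h <- split(seq_len(nrow(d)), d$height_cm)
  n <- length(per_h[[1L]])
  if (any(vapply(per_h, length, integer(1)) != n)) {
    stop_tl("height traces have unequal lengths", "tl_format_error")
  }
  time0 <- tm[per_h[[as.character(hs[1L])]]]
  temp <- matrix(NA_real_, n, length(hs))
  for (j in seq_along(hs)) {
    idx <- per_h[[as.character(hs[j])]]
    if (any(as.numeric(tm[idx]) != as.numeric(time0))) {
      stop_tl(sprintf("timestamps differ between heights %g and %g cm",
                      hs[1L], hs[j]), "tl_format_error")
    }
    temp[, j] <- d$temp_C[idx]
  }
  idx1 <- per_h[[as.character(hs[1L])]]
  solar <- if ("solar" %in% names(d)) d$solar[idx1] else NULL
  dryness <- if ("dryness" %in% names(d)) d$dryness[idx1] else NULL
  rain <- if ("rain" %in% names(d)) as.logical(d$rain[idx1]) else NULL
  tryCatch(
    microclim(time0, temp, hs, solar = solar, dryness = dryness, rain = rain),
    thermload_error = function(e) {
      stop_tl(sprintf("invalid microclimate CSV: %s", conditionMessage(e)),
              "tl_format_error")
    })
}
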