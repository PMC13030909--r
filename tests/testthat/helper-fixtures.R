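# Shared fixture builders (all fixtures are generated in code).

# A single-height microclim series at constant (or supplied) temperature.
constant_series <- function(temp, minutes = 60, step = 1, height = 0) {
  t0 <- as.POSIXct("2020-01-06 00:00:00", tz = "UTC")
  tm <- t0 + seq(0, minutes * 60, by = step * 60)
  temps <- rep_len(temp, length(tm))
  microclim(tm, matrix(temps, ncol = 1), height)
}

# A piecewise series from (temperature, duration-in-minutes) segments.
segment_series <- function(temps, durations, step = 1, height = 0) {
  stopifnot(length(temps) == length(durations))
  v <- unlist(mapply(function(T, d) rep(T, d / step), temps, durations,
                     SIMPLIFY = FALSE))
  t0 <- as.POSIXct("2020-01-06 00:00:00", tz = "UTC")
  tm <- t0 + seq(0, length(v)) * step * 60
  microclim(tm, matrix(c(v, v[length(v)]), ncol = 1), height)
}

default_pollen <- function() tdt_params(46, 3)

pkg_fixture <- function(name) {
  system.file("extdata", name, package = "thermload", mustWork = TRUE)
}

heatwave_config <- function() {
  read_pipeline_config(pkg_fixture("config_heatwave.yaml"))
}
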