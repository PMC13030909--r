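#' Pipeline run configuration
#'
#' Orchestrates a full run: a microclimate input (either a synthetic
#' [weather_scenario()] plus [profile_params()], or a microclimate CSV
#' exported from an external model), a list of life stages, and run
#' options.
#'
#' @param stages List of [stage_spec()] objects with unique names.
#'   Default [default_stages()].
#' @param scenario A [weather_scenario()] (exclusive with `csv`).
#' @param csv Path to a microclimate CSV (exclusive with `scenario`).
#' @param profile [profile_params()] used with `scenario`.
#' @param dt Integration step, minutes; > 0. Default 1.
#' @param step_minutes Sampling step for synthetic weather. Default 10.
#' @param seed Master RNG seed; per-stage sub-seeds are derived from it
#'   and the stage name, so adding a stage never perturbs the others.
#' @param write_individuals Write per-individual probability columns in
#'   trajectory CSVs (needed to recompute every summary statistic from
#'   the files). Default `TRUE`.
#' @param strict_csv Reject unsorted microclimate CSV input instead of
#'   re-sorting. Default `TRUE`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = default_stages(), scenario = NULL,
                            csv = NULL, profile = profile_params(),
                            dt = 1, step_minutes = 10, seed = 42L,
                            write_individuals = TRUE, strict_csv = TRUE) {
  if (!length(stages)) stop_tl("at least one stage is required", "tl_config_error")
  for (s in stages) {
    if (!inherits(s, "stage_spec")) {
      stop_tl("`stages` must be a list of `stage_spec` objects",
              "tl_config_error")
    }
  }
  nm <- vapply(stages, function(s) s$name, character(1))
  if (anyDuplicated(nm)) {
    stop_tl(sprintf("stage names must be unique (duplicated: %s)",
                    paste(unique(nm[duplicated(nm)]), collapse = ", ")),
            "tl_config_error")
  }
  if (is.null(scenario) == is.null(csv)) {
    stop_tl("exactly one of `scenario` or `csv` must be given",
            "tl_config_error")
  }
  if (!is.null(scenario) && !inherits(scenario, "weather_scenario")) {
    stop_tl("`scenario` must be a `weather_scenario` object", "tl_config_error")
  }
  check_finite_scalar(dt, "dt")
  if (dt <= 0) stop_tl("`dt` must be > 0", "tl_config_error")
  check_finite_scalar(seed, "seed")
  structure(list(stages = stats::setNames(stages, nm), scenario = scenario,
                 csv = csv, profile = profile, dt = dt,
                 step_minutes = step_minutes, seed = as.integer(seed),
                 write_individuals = isTRUE(write_individuals),
                 strict_csv = isTRUE(strict_csv)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Schema (see `inst/extdata/config_heatwave.yaml` for a commented
#' example): top-level keys `stages` (list of stage mappings with `name`,
#' `height_cm`, `ctmax`, `z`, optional `t_ref`, `sd_ctmax`, `sd_z`,
#' `t_cross` or `repair: off`, `n_individuals`), `input` (either
#' `scenario: {...}` with [weather_scenario()] fields or `csv: path`),
#' optional `profile` ([profile_params()] fields), `dt`, `step_minutes`,
#' `seed`, `write_individuals`, `strict_csv`.
#'
#' @param path YAML config path.
#' @return A [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop_tl(sprintf("config file not found: %s", path), "tl_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$stages)) {
    stop_tl("config field `stages` is required", "tl_config_error")
  }
  stages <- lapply(raw$stages, function(s) {
    for (f in c("name", "height_cm", "ctmax", "z")) {
      if (is.null(s[[f]])) {
        stop_tl(sprintf("stage entry is missing required field `stages[].%s`",
                        f), "tl_config_error")
      }
    }
    repair <- if (!is.null(s$t_cross)) s$t_cross
      else if (identical(s$repair, "off")) NULL
      else 31
    stage_spec(
      name = s$name, height_cm = s$height_cm,
      tdt = tdt_params(s$ctmax, s$z, t_ref = s$t_ref %||% 1),
      sd_ctmax = s$sd_ctmax %||% 1, sd_z = s$sd_z %||% 0.25,
      repair = repair, n_individuals = s$n_individuals %||% 100)
  })
  input <- raw$input
  if (is.null(input) || is.null(input$scenario) == is.null(input$csv)) {
    stop_tl("config field `input` must contain exactly one of `input.scenario` or `input.csv`",
            "tl_config_error")
  }
  scenario <- if (!is.null(input$scenario)) {
    do.call(weather_scenario, input$scenario)
  }
  profile <- if (!is.null(raw$profile)) do.call(profile_params, raw$profile)
    else profile_params()
  pipeline_config(
    stages = stages, scenario = scenario, csv = input$csv, profile = profile,
    dt = raw$dt %||% 1, step_minutes = raw$step_minutes %||% 10,
    seed = raw$seed %||% 42L,
    write_individuals = raw$write_individuals %||% TRUE,
    strict_csv = raw$strict_csv %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.traj_path <- function(out_dir, stage) {
  file.path(out_dir, sprintf("trajectory_%s.csv", stage))
}

.write_trajectory <- function(traj, path, write_individuals) {
  d <- data.frame(
    datetime = format(traj$time, .mc_time_fmt, tz = "UTC"),
    stage = traj$stage,
    height_cm = format(traj$height_cm, trim = TRUE),
    temp_C = sprintf("%.9f", traj$temp_C),
    mean_p = sprintf("%.9f", traj$mean_p))
  if (write_individuals) {
    p <- traj$p
    cols <- sprintf("p_%03d", seq_len(ncol(p)))
    for (j in seq_len(ncol(p))) d[[cols[j]]] <- sprintf("%.9f", p[, j])
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.summary_from_files <- function(files) {
  if (!length(files)) {
    stop_tl("no trajectory files found", "tl_integrity_error")
  }
  stages <- list()
  heights <- list()
  for (f in files) {
    d <- tryCatch(utils::read.csv(f, stringsAsFactors = FALSE),
                  error = function(e) {
                    stop_tl(sprintf("cannot read trajectory file %s: %s",
                                    f, conditionMessage(e)),
                            "tl_integrity_error")
                  })
    need <- c("datetime", "stage", "height_cm", "temp_C", "mean_p")
    if (!all(need %in% names(d)) || nrow(d) == 0L) {
      stop_tl(sprintf("trajectory file %s is corrupt or incomplete", f),
              "tl_integrity_error")
    }
    stage <- d$stage[1L]
    h <- d$height_cm[1L]
    pcols <- grep("^p_\\d+$", names(d), value = TRUE)
    final_mean_p <- d$mean_p[nrow(d)]
    if (length(pcols)) {
      pm <- as.matrix(d[, pcols, drop = FALSE])
      final_p <- pm[nrow(pm), ]
      frac_failed <- mean(final_p >= 1 - 1e-9)
      any_failed_t <- apply(pm >= 1 - 1e-9, 1L, any)
      t_first <- if (any(any_failed_t)) d$datetime[which(any_failed_t)[1L]]
        else NA_character_
    } else {
      frac_failed <- NA_real_
      t_first <- NA_character_
    }
    stages[[stage]] <- list(
      height_cm = h,
      final_mean_p = final_mean_p,
      fraction_failed = frac_failed,
      time_first_failure = t_first,
      peak_temp_C = max(d$temp_C))
    heights[[as.character(h)]] <- list(height_cm = h,
                                       max_temp_C = max(d$temp_C),
                                       min_temp_C = min(d$temp_C))
  }
  structure(list(stages = stages, heights = heights), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Run summary\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf(
      "  %-9s (%4g cm): final mean p = %.4f, failed = %s, peak T = %.2f degC, first failure = %s\n",
      nm, s$height_cm, s$final_mean_p,
      ifelse(is.na(s$fraction_failed), "NA",
             sprintf("%.0f%%", 100 * s$fraction_failed)),
      s$peak_temp_C, ifelse(is.na(s$time_first_failure), "none",
                            s$time_first_failure)))
  }
  invisible(x)
}

#' Run the full thermal-load pipeline
#'
#' Builds (or loads) the microclimate series, then for each stage draws
#' its population with a deterministic stage-specific sub-seed and
#' simulates damage dynamics at the stage's height. Writes one
#' trajectory CSV per stage, a `summary.json`, and a copy of the
#' resolved configuration (`config_resolved.yaml`) to `out_dir`.
#' Idempotent: identical config and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()] object (or path to a YAML config).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the config's master seed.
#' @return A `run_summary` object (invisibly), with attribute `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    stop_tl("`config` must be a `pipeline_config` object or a YAML path",
            "tl_config_error")
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  heights <- vapply(config$stages, function(s) s$height_cm, numeric(1))
  series <- if (!is.null(config$scenario)) {
    generate_microclimate(config$scenario, config$profile,
                          heights = unique(heights),
                          step_minutes = config$step_minutes)
  } else {
    read_microclimate_csv(config$csv, strict = config$strict_csv)
  }
  missing_h <- setdiff(unique(heights), series$heights)
  if (length(missing_h)) {
    stop_tl(sprintf(
      "stage height(s) %s cm not present in the microclimate series (available: %s)",
      paste(missing_h, collapse = ", "),
      paste(series$heights, collapse = ", ")), "tl_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (stage in config$stages) {
    sub <- stage_subseed(config$seed, stage$name)
    traj <- simulate_population(stage, series, dt = config$dt, seed = sub)
    .write_trajectory(traj, .traj_path(out_dir, stage$name),
                      config$write_individuals)
  }
  summary <- .summary_from_files(
    .traj_path(out_dir, vapply(config$stages, function(s) s$name,
                               character(1))))
  jsonlite::write_json(unclass(summary), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  yaml::write_yaml(.serialize_config(config),
                   file.path(out_dir, "config_resolved.yaml"))
  attr(summary, "out_dir") <- out_dir
  invisible(summary)
}

.serialize_config <- function(config) {
  list(
    stages = lapply(unname(config$stages), function(s) {
      rep <- s$repair
      c(list(name = s$name, height_cm = s$height_cm, ctmax = s$tdt$ctmax,
             z = s$tdt$z, t_ref = s$tdt$t_ref, sd_ctmax = s$sd_ctmax,
             sd_z = s$sd_z, n_individuals = s$n_individuals),
        if (is.null(rep)) list(repair = "off")
        else if (inherits(rep, "repair_params")) list(repair = unclass(rep))
        else list(t_cross = rep))
    }),
    input = if (!is.null(config$scenario)) {
      list(scenario = unclass(config$scenario))
    } else list(csv = config$csv),
    profile = unclass(config$profile),
    dt = config$dt, step_minutes = config$step_minutes, seed = config$seed,
    write_individuals = config$write_individuals,
    strict_csv = config$strict_csv)
}

#' Recompute a run summary from emitted trajectory files
#'
#' Reads the `trajectory_*.csv` files in a run output directory and
#' recomputes the per-stage summary; by construction this equals the
#' `summary.json` written by [run_pipeline()].
#'
#' @param out_dir A [run_pipeline()] output directory (or a character
#'   vector of trajectory CSV paths).
#' @return A `run_summary` object.
#' @export
summarize_run <- function(out_dir) {
  files <- if (length(out_dir) == 1L && dir.exists(out_dir)) {
    list.files(out_dir, pattern = "^trajectory_.*\\.csv$", full.names = TRUE)
  } else out_dir[file.exists(out_dir)]
  .summary_from_files(files)
}
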