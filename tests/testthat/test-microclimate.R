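test_that("vertical_offset reproduces the calibrated surface and 1 cm excesses", {
  pr <- profile_params()
  expect_equal(vertical_offset(pr, 0, solar = 1, dryness = 1), 20)
  expect_equal(vertical_offset(pr, 1, solar = 1, dryness = 1), 8)
  expect_lt(vertical_offset(pr, 50, solar = 1, dryness = 1), 0.001)

  # night: surface cools below air
  expect_equal(vertical_offset(pr, 0, solar = 0, dryness = 1), -2)

  # shade linearity: excess at shade s is (1 - s) times unshaded excess
  for (s in c(0.2, 0.6)) {
    prs <- profile_params(shade_fraction = s)
    expect_equal(vertical_offset(prs, 0, 1, 1),
                 (1 - s) * vertical_offset(pr, 0, 1, 1))
  }
  expect_equal(vertical_offset(profile_params(shade_fraction = 0.6), 0, 1, 1), 8)

  # monotone decay with height, towards zero
  hs <- c(0, 0.5, 1, 2, 5, 10, 50)
  ex <- vapply(hs, function(h) vertical_offset(pr, h, 1, 1), numeric(1))
  expect_true(all(diff(ex) < 0))
  expect_lt(ex[length(ex)], 1e-10)

  expect_error(vertical_offset(pr, 0, solar = 1.2, dryness = 1),
               class = "tl_invalid_input")
  expect_error(vertical_offset(pr, 0, solar = 1, dryness = -0.1),
               class = "tl_invalid_input")
  expect_error(profile_params(shade_fraction = 0.7), class = "tl_invalid_input")
})

test_that("apply_profile stratifies by height and preserves the air trace", {
  scn <- weather_scenario(n_days = 2, rain_days = 2)
  air <- generate_weather(scn)
  mc <- apply_profile(air, profile_params(), heights = c(0, 1, 50))
  expect_setequal(mc_heights(mc), c(0, 1, 50, 120))
  expect_identical(mc_trace(mc, 120), mc_trace(air, 120))

  day <- air$solar > 0
  expect_true(all(mc_trace(mc, 0)[day] >= mc_trace(mc, 1)[day]))
  expect_true(all(mc_trace(mc, 1)[day] >= mc_trace(mc, 50)[day]))

  # rain day: solar is zero all day, so the surface sits at the (small)
  # nocturnal deficit below air temperature instead of far above it
  expect_true(all(air$solar[air$rain] == 0))
  expect_equal(mc_trace(mc, 0)[air$rain] - mc_trace(mc, 120)[air$rain],
               rep(-2, sum(air$rain)))

  # missing solar/dryness traces are a configuration error
  bare <- microclim(air$time, matrix(mc_trace(air, 120), ncol = 1), 120)
  expect_error(apply_profile(bare, profile_params()),
               class = "tl_config_error")
})

test_that("microclimate CSV round-trips losslessly and validates on read", {
  scn <- weather_scenario(n_days = 2, rain_days = 2)
  mc <- generate_microclimate(scn, heights = c(0, 1, 50))
  path <- withr::local_tempfile(fileext = ".csv")
  write_microclimate_csv(mc, path)
  back <- read_microclimate_csv(path)
  expect_equal(back$heights, sort(mc$heights))
  expect_equal(as.numeric(back$time), as.numeric(mc$time))
  for (h in mc$heights) {
    expect_equal(mc_trace(back, h), mc_trace(mc, h), tolerance = 1e-8)
  }
  expect_equal(back$solar, mc$solar, tolerance = 1e-8)
  expect_equal(back$dryness, mc$dryness, tolerance = 1e-8)
  expect_equal(back$rain, mc$rain)

  # shuffled rows: rejected in strict mode, re-sorted otherwise
  d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  set.seed(1)
  shuffled <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d[sample(nrow(d)), ], shuffled, row.names = FALSE,
                   quote = FALSE)
  expect_error(read_microclimate_csv(shuffled, strict = TRUE),
               class = "tl_format_error")
  resorted <- read_microclimate_csv(shuffled, strict = FALSE)
  expect_equal(mc_trace(resorted, 0), mc_trace(back, 0))

  # missing required column is named in the error
  d2 <- d[, setdiff(names(d), "temp_C")]
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d2, bad, row.names = FALSE, quote = FALSE)
  err <- expect_error(read_microclimate_csv(bad), class = "tl_format_error")
  expect_match(conditionMessage(err), "temp_C")

  # unparseable datetimes are reported with row context
  d3 <- d
  d3$datetime[5] <- "not-a-date"
  bad2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d3, bad2, row.names = FALSE, quote = FALSE)
  err2 <- expect_error(read_microclimate_csv(bad2), class = "tl_format_error")
  expect_match(conditionMessage(err2), "row")
})
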