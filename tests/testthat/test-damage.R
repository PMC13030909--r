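test_that("step_damage applies the clamped net-rate update with absorbing failure", {
  p <- default_pollen()
  rp <- calibrate_repair(p, 31)
  ind <- list(tdt = p, repair = rp, damage = 0.5, failed = FALSE)

  # permissive temperature: net repair
  cooled <- step_damage(ind, 25, dt = 10)
  expect_lt(cooled$damage, 0.5)
  expect_false(cooled$failed)

  # nothing to repair: clamped at zero
  fresh <- step_damage(list(tdt = p, repair = rp, damage = 0), 25, dt = 100)
  expect_equal(fresh$damage, 0)

  # stressful temperature accumulates; D = 1 is absorbing through cool periods
  hot <- step_damage(list(tdt = p, repair = rp, damage = 0.99), 46, dt = 5)
  expect_equal(hot$damage, 1)
  expect_true(hot$failed)
  after_cool <- step_damage(hot, 10, dt = 1e5)
  expect_equal(after_cool$damage, 1)
  expect_true(after_cool$failed)

  # consistency with the analytic rates
  one <- step_damage(list(tdt = p, repair = rp, damage = 0.2), 40, dt = 2)
  expect_equal(one$damage, 0.2 + net_damage_rate(p, rp, 40) * 2,
               tolerance = 1e-12)

  expect_error(step_damage(ind, 40, dt = 0), class = "tl_invalid_input")
})

test_that("constant-temperature simulation matches the closed-form TDT failure time", {
  # repair off: time to failure equals the analytic failure time, per stage
  for (s in default_stages()) {
    for (dT in c(-3, 0, 3)) {
      Tc <- s$tdt$ctmax + dT
      ft <- failure_time(s$tdt, Tc)
      series <- constant_series(Tc, minutes = ceiling(ft * 2), step = 1)
      tr <- simulate_individual(s$tdt, NULL, series, dt = 0.1)
      expect_equal(attr(tr, "failure_time"), ft, tolerance = 1e-9)
    }
  }
})

test_that("with repair off, damage accumulates linearly at step boundaries", {
  p <- default_pollen()
  series <- constant_series(43, minutes = 8, step = 1)
  tr <- simulate_individual(p, NULL, series)
  tmin <- as.numeric(difftime(tr$time, tr$time[1], units = "mins"))
  expect_equal(tr$damage, tmin / failure_time(p, 43), tolerance = 1e-12)
  expect_equal(tr$p, tr$damage)
})

test_that("benign constant series leaves p identically zero", {
  p <- default_pollen()
  rp <- calibrate_repair(p, 31)
  tr <- simulate_individual(p, rp, constant_series(20, minutes = 600, step = 10))
  expect_true(all(tr$p == 0))
  expect_true(is.na(attr(tr, "failure_time")))
})

test_that("damaged individuals repair to near zero under sustained permissive temperature", {
  p <- default_pollen()
  rp <- calibrate_repair(p, 31)
  # net repair at 27 degC is ~6.7e-6/min: D0 = 0.5 needs ~52 days
  series <- constant_series(27, minutes = 100 * 1440, step = 60)
  tr <- simulate_individual(p, rp, series, D0 = 0.5)
  expect_lt(tr$damage[nrow(tr)], 0.01)
  # strictly decreasing until the zero clamp engages
  d <- tr$damage
  active <- d > 0
  expect_true(all(diff(d[active]) < 0))
})

test_that("a prior hot pulse brings failure forward in a recurrent pulse (ratcheting)", {
  p <- default_pollen()
  rp <- calibrate_repair(p, 31)
  # pulse at 40 degC: failure from D0 = 0 takes ~100 min
  pulse_fail_cold <- function(D0) {
    series <- constant_series(40, minutes = 200, step = 1)
    attr(simulate_individual(p, rp, series, D0 = D0), "failure_time")
  }
  t_cold <- pulse_fail_cold(0)
  expect_false(is.na(t_cold))

  # 80 min pulse -> ~0.8 damage, then one permissive day, then pulse again
  two_pulse <- segment_series(c(40, 25, 40), c(80, 1440, 300), step = 1)
  tr <- simulate_individual(p, rp, two_pulse)
  t_fail <- attr(tr, "failure_time")
  expect_false(is.na(t_fail))
  t_in_second <- t_fail - (80 + 1440)
  expect_gt(t_in_second, 0)       # survived pulse 1 and the permissive day
  expect_lt(t_in_second, t_cold)  # but fails earlier than from a cold start

  # oracle: expected failure time in pulse 2 from the analytic rates
  net40 <- net_damage_rate(p, rp, 40)
  net25 <- net_damage_rate(p, rp, 25)
  D_start2 <- 80 * net40 + 1440 * net25
  expect_equal(t_in_second, (1 - D_start2) / net40, tolerance = 1e-6)
})

test_that("draw_population is deterministic, sized, and respects degenerate sds", {
  stage <- default_stages()$pollen
  pop1 <- draw_population(stage, seed = 7)
  pop2 <- draw_population(stage, seed = 7)
  expect_identical(pop1, pop2)
  expect_equal(nrow(pop1), 100L)
  expect_gt(stats::sd(pop1$ctmax), 0)
  expect_true(all(pop1$z >= 0.5))

  pop3 <- draw_population(stage, seed = 8)
  expect_false(identical(pop1$ctmax, pop3$ctmax))

  degen <- stage_spec("pollen", 50, default_pollen(), sd_ctmax = 0, sd_z = 0)
  popd <- draw_population(degen, seed = 1)
  expect_true(all(popd$ctmax == 46) && all(popd$z == 3))
})

test_that("simulate_population averages individuals and respects bounds", {
  stage <- stage_spec("pollen", 0, default_pollen(), n_individuals = 25)
  series <- segment_series(c(28, 41, 25), c(300, 120, 300), step = 5)
  traj <- simulate_population(stage, series, seed = 3)
  expect_equal(dim(traj$p), c(length(traj$time), 25L))
  expect_true(all(traj$p >= 0 & traj$p <= 1))
  expect_equal(traj$mean_p, rowMeans(traj$p))
  # absorbing: per-individual p never decreases after reaching 1
  for (j in seq_len(ncol(traj$p))) {
    hit <- which(traj$p[, j] >= 1)
    if (length(hit)) expect_true(all(traj$p[hit[1]:nrow(traj$p), j] == 1))
  }

  # zero-variance population equals the single-individual trajectory
  degen <- stage_spec("pollen", 0, default_pollen(), sd_ctmax = 0, sd_z = 0,
                      n_individuals = 10)
  trajd <- simulate_population(degen, series, seed = 1)
  single <- simulate_individual(default_pollen(),
                                calibrate_repair(default_pollen(), 31),
                                series)
  expect_equal(trajd$mean_p, single$p, tolerance = 1e-12)

  # monotone response to a uniform +5 degC shift (paired seed)
  hot <- simulate_population(stage, mc_shift(series, 5), seed = 3)
  expect_gte(hot$mean_p[length(hot$mean_p)],
             traj$mean_p[length(traj$mean_p)])

  # missing height is a configuration error naming availability
  stage50 <- stage_spec("pollen", 50, default_pollen())
  expect_error(simulate_population(stage50, series), class = "tl_config_error")
})
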