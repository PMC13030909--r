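test_that("failure_time and tolerated_temperature match the closed form and invert", {
  p <- default_pollen()

  # frozen closed-form examples
  expect_equal(failure_time(p, 46), 1)
  expect_equal(failure_time(p, 43), 10)
  expect_equal(failure_time(p, 49), 0.1)
  expect_equal(tolerated_temperature(p, 1), 46)
  expect_equal(tolerated_temperature(p, 10), 43)

  # round trip identity over a temperature grid
  Tg <- seq(0, 70, by = 0.5)
  expect_equal(tolerated_temperature(p, failure_time(p, Tg)), Tg,
               tolerance = 1e-9)

  # log-linearity: second differences of log10 failure time vanish
  lf <- log10(failure_time(p, Tg))
  expect_lt(max(abs(diff(diff(lf)))), 1e-10)

  # monotonicity
  expect_true(all(diff(failure_time(p, Tg)) < 0))
  expect_true(all(diff(damage_rate(p, Tg)) > 0))

  # t_ref scales durations
  p2 <- tdt_params(46, 3, t_ref = 5)
  expect_equal(failure_time(p2, 46), 5)

  expect_error(failure_time(p, NA_real_), class = "tl_invalid_input")
  expect_error(failure_time(p, Inf), class = "tl_invalid_input")
  expect_error(tolerated_temperature(p, 0), class = "tl_invalid_input")
  expect_error(tdt_params(46, -1), class = "tl_invalid_input")
})

test_that("damage_rate is the reciprocal failure time with fixed per-degree escalation", {
  p <- default_pollen()
  expect_equal(damage_rate(p, 46), 1)
  expect_equal(damage_rate(p, 43), 0.1)
  # escalation ratio is temperature-independent: 10^(1/z)
  for (T in c(20, 31, 40, 55)) {
    expect_equal(damage_rate(p, T + 1) / damage_rate(p, T), 10^(1 / 3),
                 tolerance = 1e-12)
  }
  # constant exposure of length failure_time(T) accumulates exactly 1
  for (T in c(35, 46, 50)) {
    expect_equal(damage_rate(p, T) * failure_time(p, T), 1)
  }
})

test_that("numerically integrating damage_rate reproduces failure_time (oracle)", {
  p <- default_pollen()
  for (T in c(43, 46, 49)) {
    dt <- failure_time(p, T) / 1e4
    rate <- damage_rate(p, T)
    n_steps <- 0
    D <- 0
    while (D < 1) {
      D <- D + rate * dt
      n_steps <- n_steps + 1
    }
    expect_lte(abs(n_steps * dt - failure_time(p, T)), 2 * dt)
  }
})

test_that("fit_tdt recovers exact parameters from collinear points", {
  fit <- fit_tdt(tdt_assay(c(40, 43, 46), c(100, 10, 1)))
  expect_equal(fit$params$ctmax, 46, tolerance = 1e-9)
  expect_equal(fit$params$z, 3, tolerance = 1e-9)
  expect_equal(fit$sigma, 0, tolerance = 1e-9)
  expect_equal(fit$n_obs, 3L)

  # line through two points
  fit2 <- fit_tdt(tdt_assay(c(40, 43), c(100, 10)))
  expect_equal(fit2$params$ctmax, 46, tolerance = 1e-9)
  expect_equal(fit2$params$z, 3, tolerance = 1e-9)
  expect_equal(fit2$sigma, 0, tolerance = 1e-9)
})

test_that("fit_tdt rejects degenerate and non-TDT designs", {
  expect_error(fit_tdt(tdt_assay(c(43, 43, 43), c(1, 2, 3))),
               class = "tl_degenerate_design")
  # failure time increasing with temperature is not TDT behaviour
  expect_error(fit_tdt(tdt_assay(c(40, 43, 46), c(1, 10, 100))),
               class = "tl_non_tdt")
  expect_error(tdt_assay(c(40, 43), c(-1, 10)), class = "tl_invalid_input")
})

test_that("fit_tdt recovers generated parameters within stated bounds", {
  truth <- default_pollen()
  assay <- generate_tdt_assay(truth, c(42, 44, 46, 48), reps_per_temp = 10,
                              noise_sd = 0.1, seed = 1)
  expect_equal(nrow(assay), 40L)
  fit <- fit_tdt(assay)
  expect_lt(abs(fit$params$ctmax - 46), 0.5)
  expect_lt(abs(fit$params$z - 3) / 3, 0.10)
  expect_gt(fit$se_z, 0)
  expect_gt(fit$se_ctmax, 0)
})

test_that("fit_tdt bias shrinks as replicates grow (10 vs 100 reps)", {
  truth <- default_pollen()
  err <- function(reps) {
    z_err <- vapply(1:20, function(s) {
      a <- generate_tdt_assay(truth, c(42, 44, 46, 48), reps_per_temp = reps,
                              noise_sd = 0.1, seed = s)
      abs(fit_tdt(a)$params$z - 3)
    }, numeric(1))
    mean(z_err)
  }
  expect_lt(err(100), err(10))
})
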