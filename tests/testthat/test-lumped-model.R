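# Forward model: closed-form identities of the lumped-capacitance law.

test_that("heating law reproduces its closed-form identities", {
  p <- std_params(efficiency = 0.80)

  expect_identical(predict_delta_t(p, 0), 0)
  expect_equal(predict_delta_t(std_params(0), c(0, 50, 1e4)), rep(0, 3))

  # steady state for the standard rig: 300 * 0.196 * (1 - 10^-0.56) * 0.8
  # / 4.184, evaluated independently with 30-digit arithmetic
  expect_equal(steady_state_delta_t(p), 8.14629736603663, tolerance = 1e-12)
  expect_equal(predict_delta_t(p, 1e6), steady_state_delta_t(p),
               tolerance = 1e-12)

  # monotone nondecreasing, strictly below steady state at finite t
  t_grid <- seq(0, 3000, by = 30)
  dts <- predict_delta_t(p, t_grid)
  expect_true(all(diff(dts) > 0))
  expect_true(all(dts < steady_state_delta_t(p)))

  # within 1e-4 of the plateau after 10 tau
  expect_lt(steady_state_delta_t(p) - predict_delta_t(p, 10 * p$time_constant),
            1e-4 * steady_state_delta_t(p))
})

test_that("steady state is linear in power and efficiency, inverse in heat capacity", {
  base <- std_params(0.4)
  expect_equal(steady_state_delta_t(std_params(0.8)),
               2 * steady_state_delta_t(base))
  expect_equal(steady_state_delta_t(std_params(0.4, laser_power = 0.392)),
               2 * steady_state_delta_t(base))
  doubled <- std_params(0.4, components = list(heat_component("water", 2, 4.184)))
  expect_equal(steady_state_delta_t(doubled), steady_state_delta_t(base) / 2)
})

test_that("invalid model arguments are rejected", {
  expect_error(predict_delta_t(std_params(0.5), -1),
               class = "phototherm_argument_error")
  expect_error(lumped_params(0.196, 0.56, 1.2, 300),
               class = "phototherm_argument_error")
  expect_error(lumped_params(0.196, 0.56, 0.5, -10),
               class = "phototherm_argument_error")
  expect_error(lumped_params(0.196, 0.56, 0.5, 300, components = list()),
               class = "phototherm_argument_error")
  expect_error(heat_component("water", 0, 4.184),
               class = "phototherm_argument_error")
  expect_error(thermal_trace(c(0, 60), c(25, 26, 27), 25),
               class = "phototherm_argument_error")
})

test_that("cycle simulation chains heating and cooling phases correctly", {
  # no absorbed power: flat at ambient
  flat <- simulate_cycles(std_params(0), 900, 900, n_cycles = 2, dt = 60)
  expect_equal(flat$temps, rep(flat$ambient_temp, length(flat$times)))

  # one time constant into heating: 1 - e^-1 of the plateau
  p <- std_params(0.8, tau = 300)
  tr <- simulate_cycles(p, 900, 900, dt = 60)
  expect_equal(tr$temps[tr$times == 300] - p$ambient_temp,
               (1 - exp(-1)) * steady_state_delta_t(p))

  # long relaxation returns to ambient
  relax <- simulate_cycles(p, 900, 20 * p$time_constant, dt = 60)
  expect_lt(abs(relax$temps[length(relax$temps)] - p$ambient_temp), 1e-3)

  expect_error(simulate_cycles(p, 900, 900, dt = 900),
               class = "phototherm_argument_error")
})

test_that("repeated irradiation cycles reach equal peak temperatures", {
  # four 15-min on / 15-min off cycles; with tau = 150 s the sample relaxes
  # almost fully between cycles, so the per-cycle maxima agree within 1%
  p <- std_params(0.8, tau = 150)
  tr <- simulate_cycles(p, 900, 900, n_cycles = 4, dt = 30)

  # independent oracle: chain the phase endpoints explicitly
  ss <- steady_state_delta_t(p)
  expected_peaks <- numeric(4)
  d <- 0
  for (cyc in 1:4) {
    peak <- ss + (d - ss) * exp(-900 / 150)
    expected_peaks[cyc] <- peak
    d <- peak * exp(-900 / 150)
  }

  period <- 1800
  measured <- vapply(1:4, function(cyc) {
    sel <- tr$times >= (cyc - 1) * period & tr$times <= cyc * period
    max(tr$temps[sel]) - p$ambient_temp
  }, numeric(1))

  expect_equal(measured, expected_peaks, tolerance = 1e-10)
  expect_lt(diff(range(measured)) / max(measured), 0.01)
  expect_equal(tr$metadata$cycle_peak_rise, expected_peaks, tolerance = 1e-10)
})
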