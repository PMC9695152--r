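# Efficiency estimation pipeline: plateau, cooling fit, closure, balance.

test_that("steady-state rise extraction behaves on plateaued and degenerate traces", {
  amb <- 25
  flat <- thermal_trace(seq(0, 600, 60), rep(amb, 11), amb)
  expect_equal(delta_t_max(flat), 0)

  # noiseless model trace with a 22 degC plateau, heated to 10 tau
  p22 <- std_params(1, tau = 300,
                    laser_power = 22 * 4.184 / (300 * (1 - 10^-0.56)))
  expect_equal(steady_state_delta_t(p22), 22, tolerance = 1e-12)
  tr <- simulate_cycles(p22, on_duration = 3000, off_duration = 600, dt = 60)
  expect_equal(delta_t_max(tr), 22, tolerance = 0.01 / 22)

  two <- thermal_trace(c(0, 60), c(26, 27), 25, laser_off_time = 60)
  expect_error(delta_t_max(two), class = "phototherm_insufficient_data")
})

test_that("cooling linearization recovers the time constant", {
  amb <- 25
  # exact exponential decay theta = exp(-t/100) sampled every 60 s
  times <- seq(0, 600, by = 60)
  tr <- thermal_trace(times, amb + 20 * exp(-times / 100), amb,
                      laser_on_time = 0, laser_off_time = 0)
  fit <- estimate_tau(tr)
  expect_equal(fit$tau, 100, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  # sigma = 0.1 degC camera noise on a 20 degC decay: within 5% of truth and
  # within 2% of an independent nonlinear least-squares fit
  set.seed(1)
  times <- seq(0, 900, by = 60)
  rise <- ifelse(times <= 300, 20, 20 * exp(-(times - 300) / 100))
  noisy <- thermal_trace(times, amb + rise + rnorm(length(times), sd = 0.1),
                         amb, laser_on_time = 0, laser_off_time = 300)
  fit_n <- estimate_tau(noisy)
  expect_lt(abs(fit_n$tau - 100) / 100, 0.05)
  cool <- noisy$times >= 300
  df <- data.frame(t = noisy$times[cool] - 300, y = noisy$temps[cool])
  oracle <- stats::nls(y ~ amb + A * exp(-t / tau), df,
                       start = list(A = 18, tau = 80))
  expect_lt(abs(fit_n$tau - coef(oracle)[["tau"]]) / coef(oracle)[["tau"]],
            0.02)

  no_cooling <- thermal_trace(times, amb + rise, amb, laser_off_time = NA)
  expect_error(estimate_tau(no_cooling),
               class = "phototherm_insufficient_data")
})

test_that("heat-transfer closure and water-control calibration are exact arithmetic", {
  expect_equal(estimate_hA(300, water_only()), 4.184 / 300, tolerance = 1e-12)
  expect_equal(estimate_hA(300, water_only()), 0.013947, tolerance = 1e-4)
  expect_equal(estimate_hA(600, water_only()),
               estimate_hA(300, water_only()) / 2)
  expect_equal(estimate_hA(1, list(heat_component("unit", 1, 1))), 1)
  expect_error(estimate_hA(0, water_only()),
               class = "phototherm_argument_error")
  expect_error(estimate_hA(300, list()), class = "phototherm_argument_error")

  amb <- 25
  times <- seq(0, 900, 60)
  still_water <- thermal_trace(times, rep(amb, length(times)), amb,
                               laser_off_time = 600)
  expect_equal(calibrate_zeta(still_water, 0.0139467, 0.196), 0)

  warm_water <- thermal_trace(times, amb + pmin(times / 300, 1), amb,
                              laser_off_time = 900)
  expect_equal(calibrate_zeta(warm_water, 4.184 / 300, 0.196),
               (4.184 / 300) / 0.196, tolerance = 1e-12)
  expect_equal(calibrate_zeta(warm_water, 4.184 / 300, 0.196), 0.0712,
               tolerance = 1e-3)
  expect_error(calibrate_zeta(warm_water, 1, 0.5),
               class = "phototherm_calibration_error")
})

test_that("energy balance returns exact eta in the balanced and parasitic-only limits", {
  # perfectly balanced absorber: eta = 1
  p1 <- std_params(1)
  tr1 <- generate_trace(p1)
  est1 <- estimate_eta(tr1, p1$laser_power, p1$absorbance,
                       components = p1$components)
  expect_equal(est1$eta, 1, tolerance = 1e-9)

  # all heating parasitic: using the trace itself as water control drives the
  # numerator hA dT - I zeta to zero, hence eta = 0
  p0 <- lumped_params(0.196, 0.56, 0, 300, parasitic_power = 0.02,
                      components = water_only())
  tr0 <- generate_trace(p0)
  est0 <- estimate_eta(tr0, 0.196, 0.56, components = water_only(),
                       water_trace = tr0)
  expect_equal(est0$eta, 0, tolerance = 1e-9)
  expect_equal(est0$zeta, 0.02 / 0.196, tolerance = 1e-6)

  expect_error(estimate_eta(tr1, 0.196, absorbance = 0),
               class = "phototherm_argument_error")
  no_cool <- thermal_trace(seq(0, 900, 60),
                           25 + predict_delta_t(p1, seq(0, 900, 60)), 25,
                           laser_off_time = NA)
  expect_error(estimate_eta(no_cool, 0.196, 0.56),
               class = "phototherm_insufficient_data")
})

test_that("noiseless round trips recover eta across the parameter grid", {
  for (eta in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    for (tau in c(60, 300, 600)) {
      p <- std_params(eta, tau = tau)
      # heat to >= 10 tau so the plateau is genuinely reached
      tr <- simulate_cycles(p, on_duration = 10 * tau, off_duration = 3 * tau,
                            dt = tau / 10)
      est <- estimate_eta(tr, p$laser_power, p$absorbance,
                          components = p$components)
      expect_lt(abs(est$eta - eta), 1e-3)
      expect_equal(est$tau, tau, tolerance = 1e-6)
    }
  }
})

test_that("noisy estimates are unbiased and preserve the sample ordering", {
  p <- std_params(0.8)
  etas <- vapply(1:200, function(s) {
    tr <- generate_trace(p, noise = noise_spec(0.2, seed = s))
    suppressWarnings(
      estimate_eta(tr, p$laser_power, p$absorbance,
                   components = p$components)$eta
    )
  }, numeric(1))
  expect_lt(abs(mean(etas) - 0.8), 0.05)

  # the four samples of the study, simulated and re-estimated, keep their
  # strict ordering 780 > 690 > 890 > 534
  truth <- c(AuNTs780 = 0.80, AuNTs690 = 0.73, AuNTs890 = 0.64,
             AuNSs534 = 0.12)
  ests <- vapply(truth, function(eta) {
    tr <- generate_trace(std_params(eta))
    estimate_eta(tr, 0.196, 0.56, components = water_only())$eta
  }, numeric(1))
  expect_true(all(diff(ests) < 0))

  # monotone in the observed rise at fixed everything else
  expect_true(all(diff(rev(ests)) > 0))

  # strongly absorbing limit: eta -> hA dTmax / I at zeta = 0
  tr <- generate_trace(p)
  est_sat <- estimate_eta(tr, p$laser_power, absorbance = 6,
                          components = p$components)
  expect_equal(est_sat$eta,
               est_sat$hA * est_sat$delta_t_max / p$laser_power,
               tolerance = 1e-5)
})

test_that("out-of-range eta is reported with a warning, not clipped", {
  p <- std_params(0.9)
  tr <- generate_trace(p)
  # overstated absorbance cannot explain the rise: eta > 1
  expect_warning(
    est <- estimate_eta(tr, p$laser_power, absorbance = 0.2,
                        components = p$components),
    "outside"
  )
  expect_gt(est$eta, 1)
  expect_false(est$eta_in_range)
})
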