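# Finite-difference phantom simulator: geometry, stability, conservation,
# and agreement with the analytic heat kernel.

test_that("phantom geometry matches the layered skin configuration", {
  g <- build_phantom()  # 96 x 64 at 0.25 mm
  expect_equal(g$nx, 96)
  expect_equal(g$ny, 64)
  # 1.25 mm puncture spans 5 cells at 0.25 mm
  expect_equal(sum(g$inclusion[1, ]), 5)
  # epidermal band is 4 mm = 16 rows (inclusion counts as epidermal depth)
  expect_equal(sum(g$material[, 1] == "epidermal"), 16)
  expect_true(all(g$material[17:64, ] == "dermal"))
  # inclusion confined to the epidermal band
  expect_false(any(g$inclusion[17:64, ]))

  # halving dx doubles cell counts, physical extents unchanged
  g2 <- build_phantom(nx = 192, ny = 128, dx_mm = 0.125)
  expect_equal(sum(g2$inclusion[1, ]), 10)
  expect_equal(sum(g2$material[, 1] == "epidermal"), 32)
  expect_equal(g2$ny * g2$dx, g$ny * g$dx)

  expect_error(build_phantom(inclusion_width_mm = 0),
               class = "phototherm_argument_error")
  expect_error(build_phantom(inclusion_depth_mm = 6),
               class = "phototherm_argument_error")
  expect_error(build_phantom(ny = 32),
               class = "phototherm_argument_error")
})

test_that("unstable time steps are rejected with the computed bound", {
  g <- uniform_grid(16)
  bound <- stability_limit(g)
  expect_equal(bound, (0.25e-3)^2 * 4.18e6 / (4 * 0.6))
  expect_error(
    simulate_heating(g, beam_source(0), duration = 10, dt = 1.5 * bound,
                     frame_interval = 10),
    "stability"
  )
})

test_that("source-free insulated runs are constant, conservative, and extremum-bounded", {
  # constant field stays constant
  g <- uniform_grid(16)
  run <- simulate_heating(g, beam_source(0), duration = 5, frame_interval = 1)
  for (f in run$frames) expect_equal(f, matrix(25, 16, 16))

  # random initial field: energy conserved, extrema never grow
  set.seed(11)
  g2 <- uniform_grid(16, initial_temp = matrix(runif(256, 20, 40), 16, 16))
  run2 <- simulate_heating(g2, beam_source(0), duration = 5,
                           frame_interval = 1)
  cap <- g2$rho_c * g2$dx^2
  e0 <- sum(cap * g2$temps)
  for (f in run2$frames) {
    expect_lt(abs(sum(cap * f) - e0) / e0, 1e-6)
  }
  maxima <- vapply(run2$frames, max, numeric(1))
  minima <- vapply(run2$frames, min, numeric(1))
  expect_true(all(diff(maxima) <= 1e-12))
  expect_true(all(diff(minima) >= -1e-12))

  audit <- energy_audit(run2)
  expect_equal(audit$input_J, 0)
  expect_lt(abs(audit$stored_J), 1e-9)
})

test_that("insulated source runs store exactly the deposited energy", {
  # all-inclusion grid: mean temperature rises linearly at P / sum(cap)
  g <- uniform_grid(16, material = "inclusion")
  b <- beam_source(power = 0.05, spot_diameter_mm = 50)
  run <- simulate_heating(g, b, duration = 30, frame_interval = 10)
  cap_total <- sum(g$rho_c * g$dx^2)
  means <- vapply(run$frames, mean, numeric(1))
  expect_equal(diff(means), rep(0.05 * 10 / cap_total, 3), tolerance = 1e-9)

  audit <- energy_audit(run)
  expect_equal(audit$input_J, 0.05 * 30, tolerance = 1e-12)
  expect_lt(abs(audit$stored_J - audit$input_J) / audit$input_J, 0.01)
  expect_equal(audit$boundary_loss_J, 0)

  # layered phantom with the NIR beam: same bookkeeping
  ph <- build_phantom()
  bp <- beam_source(0.196, absorbed_fraction = 1 - 10^-0.56, efficiency = 0.8)
  run2 <- simulate_heating(ph, bp, duration = 60, frame_interval = 60)
  a2 <- energy_audit(run2)
  expect_lt(abs(a2$stored_J - a2$input_J) / a2$input_J, 0.01)
})

test_that("convective boundaries account for the missing energy", {
  g <- uniform_grid(24, material = "inclusion",
                    boundary = list(type = "convective", h = 50, T_ext = 25))
  b <- beam_source(power = 0.05, spot_diameter_mm = 50)
  run <- simulate_heating(g, b, duration = 120, frame_interval = 30)
  a <- energy_audit(run)
  expect_gt(a$boundary_loss_J, 0)
  expect_lt(abs(a$input_J - a$stored_J - a$boundary_loss_J) / a$input_J, 0.01)

  # storage rate decays as the run approaches the convective steady state
  means <- vapply(run$frames, mean, numeric(1))
  expect_lt(diff(utils::tail(means, 2)), diff(means[1:2]))
})

test_that("a point-like pulse relaxes to the analytic heat kernel", {
  n <- 64; dx <- 0.25e-3
  alpha <- 0.6 / 4.18e6
  t0 <- 3.5; t_ev <- 10
  sig0sq <- 2 * alpha * t0
  ctr <- (n + 1) / 2
  r2 <- (outer(seq_len(n), rep(1, n)) - ctr)^2 +
    (outer(rep(1, n), seq_len(n)) - ctr)^2
  r2 <- r2 * dx^2
  g <- uniform_grid(n, initial_temp = 25 + 10 * exp(-r2 / (2 * sig0sq)))
  run <- simulate_heating(g, beam_source(0), duration = t_ev,
                          frame_interval = t_ev)
  sigtsq <- sig0sq + 2 * alpha * t_ev
  analytic <- 25 + 10 * (sig0sq / sigtsq) * exp(-r2 / (2 * sigtsq))
  field <- attr(run, "final_field")
  rel_rms <- sqrt(mean((field - analytic)^2)) / (max(analytic) - 25)
  expect_lt(rel_rms, 0.02)
})

test_that("heating stays local before the diffusion time of 2 mm", {
  g <- build_phantom()
  b <- beam_source(1, absorbed_fraction = 1 - 10^-0.56, efficiency = 0.8)
  alpha <- 0.6 / 4.18e6
  t_arrive <- (2e-3)^2 / (4 * alpha)
  run <- simulate_heating(g, b, duration = t_arrive,
                          frame_interval = t_arrive)
  field <- attr(run, "final_field")
  rise_inc <- max(field[g$inclusion]) - 25
  dist <- distance_to_mask(g$inclusion)
  far <- dist * g$dx >= 2e-3
  expect_lt((max(field[far]) - 25) / rise_inc, 0.10)
})

test_that("beam power calibration hits the target hotspot rise", {
  g <- build_phantom(nx = 48, ny = 48, dx_mm = 0.25)
  b <- beam_source(1, absorbed_fraction = 0.7, efficiency = 0.8)
  cal <- calibrate_inclusion_power(g, b, target_rise = 5, at_time = 60)
  run <- simulate_heating(g, cal, duration = 60, frame_interval = 60)
  field <- attr(run, "final_field")
  expect_equal(max(field[g$inclusion]) - 25, 5, tolerance = 0.01)
})
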