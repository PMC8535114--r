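sp <- test_spec()
arr <- test_array()
cfg <- test_config()
basis <- sensor_basis_for(cfg, arr)

test_that("synthetic frames are exact without noise and reproducible with", {
  pose <- magnet_pose(c(0.015, -0.02, 0.028), heading_from_angles(1.1, 0.2))
  st <- capsule_state(pose)
  f <- synth_sensor_frame(st, rep(0, 10), arr, sp, basis, noise_sigma = 0,
                          quantize = FALSE)
  expect_lt(max(abs(f$readings - dipole_field_z(pose, sp,
                                                arr$positions))), 1e-15)
  f1 <- synth_sensor_frame(st, rep(1, 10), arr, sp, basis, rng_seed = 77)
  f2 <- synth_sensor_frame(st, rep(1, 10), arr, sp, basis, rng_seed = 77)
  expect_identical(f1$readings, f2$readings)
})

test_that("injected noise has the configured standard deviation", {
  pose <- magnet_pose(c(0, 0, 0.03), c(0, 0, 1))
  st <- capsule_state(pose)
  clean <- synth_sensor_frame(st, rep(0, 10), arr, sp, basis,
                              noise_sigma = 0, quantize = FALSE)
  sigma <- 5e-5
  set.seed(123)
  # 300 frames x 36 sensors ~ 1e4 noise draws
  devs <- replicate(300, {
    f <- synth_sensor_frame(st, rep(0, 10), arr, sp, basis,
                            noise_sigma = sigma, quantize = FALSE)
    f$readings - clean$readings
  })
  expect_lt(abs(sd(devs) - sigma) / sigma, 0.02)
})

test_that("dynamics hold still with no currents and never move below the
           friction threshold", {
  st <- capsule_state(magnet_pose(c(0, 0, 0.025), c(1, 0, 0)))
  env <- sim_environment("free_space")
  st2 <- step_dynamics(st, rep(0, 10), env, cfg, sp, dt = 0.05)
  expect_identical(st2$pose$position, st$pose$position)
  expect_identical(st2$pose$heading, st$pose$heading)
  expect_equal(st2$time, 0.05)
  # large friction threshold: capsule pinned despite a strong gradient
  sticky <- sim_environment("free_space", friction_threshold_force = 10)
  X <- build_actuation_matrix(cfg, c(0, 0, 0.025), c(1, 0, 0))
  i <- allocate_currents(X, command_to_desired(0, 0, 0.05), sv_cutoff = 1e-3)
  st3 <- step_dynamics(st, i, sticky, cfg, sp, dt = 0.05)
  expect_identical(st3$pose$position, st$pose$position)
  expect_error(step_dynamics(st, rep(0, 10), env, cfg, sp, dt = 0.5),
               "dt")
})

test_that("a uniform field aligns the heading within five time constants", {
  # Helmholtz pair only: pure field at the centre, no force
  i_hh <- c(1, 1, rep(0, 8))
  b <- ema_field(cfg, i_hh, c(0, 0, 0.025))
  i_hh <- i_hh * 5e-3 / sqrt(sum(b^2)) # scale to the 5 mT reference
  env <- sim_environment("free_space")
  st <- capsule_state(magnet_pose(c(0, 0, 0.025), c(1, 0, 0))) # 90 deg off
  tau <- 0.05
  for (k in 1:10) { # 10 x dt = 0.5 s = 10 tau >= 5 tau
    st <- step_dynamics(st, i_hh, env, cfg, sp, dt = 0.05, tau_align = tau)
  }
  expect_lt(sqrt(sum((st$pose$position - c(0, 0, 0.025))^2)), 1e-6)
  expect_gt(sum(st$pose$heading * c(0, 0, 1)), cos(1 * pi / 180))
})

test_that("translation runs at the exact overdamped terminal velocity", {
  env <- sim_environment("free_space", drag_coefficient = 3.5)
  st <- capsule_state(magnet_pose(c(0, 0, 0.025), c(1, 0, 0)))
  y <- 0
  X <- build_actuation_matrix(cfg, st$pose$position,
                              heading_from_angles(y, 0))
  i <- allocate_currents(X, command_to_desired(y, 0, 0.05),
                         sv_cutoff = 1e-3)
  G <- field_gradient_tensor(cfg, i, st$pose$position)
  # heading already aligned with the commanded field: force is known
  st2 <- step_dynamics(st, i, env, cfg, sp, dt = 0.05)
  f_expect <- magnetic_force(sp, st2$pose$heading,
                             field_gradient_tensor(cfg, i,
                                                   st$pose$position))
  v_expect <- sqrt(sum(f_expect^2)) / 3.5
  expect_equal(sqrt(sum(st2$velocity^2)), v_expect, tolerance = 1e-12)
})

test_that("tube mode projects motion onto the centerline and confines the
           capsule", {
  line <- rbind(c(-0.04, 0, 0.025), c(0.04, 0, 0.025))
  env <- sim_environment("tube", tube_centerline = line,
                         tube_radius = 0.004)
  st <- capsule_state(magnet_pose(c(0, 0.002, 0.025), c(1, 0, 0)))
  y <- pi / 4 # push diagonally; only the x-component should survive
  X <- build_actuation_matrix(cfg, st$pose$position,
                              heading_from_angles(y, 0))
  i <- allocate_currents(X, command_to_desired(y, 0, 0.05),
                         sv_cutoff = 1e-3)
  st2 <- step_dynamics(st, i, env, cfg, sp, dt = 0.05)
  expect_equal(st2$pose$position[2], st$pose$position[2], tolerance = 1e-12)
  expect_gt(st2$pose$position[1], st$pose$position[1])
})

test_that("the U-shaped path has the declared geometry", {
  path <- generate_ushape_path(extent = 0.08, spacing = 0.005, gap = 0.04)
  roi <- cfg$roi
  expect_true(all(path[, 1] >= roi$xlim[1] & path[, 1] <= roi$xlim[2]))
  expect_true(all(path[, 2] >= roi$ylim[1] & path[, 2] <= roi$ylim[2]))
  # ends on opposite legs
  expect_equal(path[1, 2], -0.02, tolerance = 1e-12)
  expect_equal(path[nrow(path), 2], 0.02, tolerance = 1e-12)
  # halving the spacing roughly doubles the waypoint count
  fine <- generate_ushape_path(spacing = 0.0025)
  expect_gt(nrow(fine) / nrow(path), 1.8)
  expect_lt(nrow(fine) / nrow(path), 2.2)
  # polyline arc length matches legs + semicircle within 1 %
  seglen <- sum(sqrt(rowSums(diff(path)^2)))
  expect_lt(abs(seglen - attr(path, "arc_length")) /
              attr(path, "arc_length"), 0.01)
})

test_that("a straight noiseless segment is tracked to the endpoint", {
  path <- cbind(seq(-0.04, 0.04, by = 0.005), 0, 0.025)
  env <- sim_environment("free_space")
  log <- run_closed_loop(path, env, cfg, arr, sp,
                         controller = list(noise_sigma = 0), seed = 4)
  final <- c(tail(log$x, 1), tail(log$y, 1), tail(log$z, 1))
  expect_lt(1e3 * sqrt(sum((final - path[nrow(path), ])^2)), 1 + 5)
  # within the 5 mm capture radius plus 1 mm overshoot allowance
  expect_lt(attr(log, "summary")$mean_error_mm, 0.05)
  # estimator and plant agree at every tick (plant/estimator consistency)
  expect_lt(1e3 * max(log$loc_error), 0.05)
})

test_that("closed-loop runs are identical under the same seed", {
  path <- cbind(seq(-0.03, 0.01, by = 0.005), 0, 0.025)
  env <- sim_environment("free_space")
  l1 <- run_closed_loop(path, env, cfg, arr, sp, seed = 9)
  l2 <- run_closed_loop(path, env, cfg, arr, sp, seed = 9)
  expect_identical(as.data.frame(l1), as.data.frame(l2))
})
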