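sp <- test_spec()
arr <- test_array()
cfg <- test_config()
basis <- sensor_basis_for(cfg, arr)

frame_for <- function(pose, currents = rep(0, 10), sigma = 0, seed = NULL,
                      quantize = FALSE) {
  synth_sensor_frame(capsule_state(pose), currents, arr, sp, basis,
                     noise_sigma = sigma, rng_seed = seed,
                     quantize = quantize)
}

test_that("compensation removes the coil field exactly on synthetic frames", {
  pose <- magnet_pose(c(0.02, -0.01, 0.03),
                      heading_from_angles(0.8, 0.2))
  # zero currents: compensation is the identity
  f0 <- frame_for(pose)
  expect_identical(compensate(f0, basis), f0$readings)
  # active coils: cancellation to machine precision
  i <- c(5, -3, 8, 8, -6, -6, 4, 4, -2, -2)
  f1 <- frame_for(pose, currents = i)
  hm <- compensate(f1, basis)
  truth <- dipole_field_z(pose, sp, arr$positions)
  expect_lt(max(abs(hm - truth)), 1e-15)
  expect_error(compensate(f1, basis[1:10, ]), "36 readings")
})

test_that("a mis-scaled basis leaves proportional contamination", {
  pose <- magnet_pose(c(0, 0, 0.025), c(1, 0, 0))
  i <- rep(5, 10)
  f <- frame_for(pose, currents = i)
  ema_at_sensors <- as.numeric(basis %*% i)
  hm_bad <- compensate(f, basis * 1.01)
  truth <- dipole_field_z(pose, sp, arr$positions)
  resid <- hm_bad - truth
  # residual is -1 % of the coil field at each sensor
  expect_equal(resid, -0.01 * ema_at_sensors, tolerance = 1e-9)
})

test_that("residuals vanish at the truth and grow away from it", {
  pose <- magnet_pose(c(0.01, 0.005, 0.03), heading_from_angles(0.5, 0.1))
  f <- frame_for(pose)
  hm <- compensate(f, basis)
  ang <- angles_from_heading(pose$heading)
  truth_params <- c(pose$position, ang[["yaw"]], ang[["pitch"]])
  r0 <- pose_residuals(truth_params, hm, arr, sp)
  expect_lt(max(abs(r0)), 1e-15)
  r1 <- pose_residuals(truth_params + c(0.01, 0, 0, 0, 0), hm, arr, sp)
  expect_gt(attr(r1, "cost"), attr(r0, "cost"))
  expect_error(pose_residuals(c(0, 0, 0.001, 0, 0), hm, arr, sp), "5 mm")
})

test_that("the coarse-grid cost surface bottoms out at the true position", {
  pose <- magnet_pose(c(-0.015, 0.02, 0.022), c(1, 0, 0))
  f <- frame_for(pose)
  hm <- compensate(f, basis)
  xs <- seq(-0.05, 0.05, by = 0.005)
  zs <- seq(0.005, 0.045, by = 0.005)
  grid <- expand.grid(x = xs, y = xs, z = zs)
  costs <- apply(grid, 1, function(g) {
    attr(pose_residuals(c(g[1], g[2], g[3], 0, 0), hm, arr, sp), "cost")
  })
  best <- grid[which.min(costs), ]
  expect_lt(max(abs(as.numeric(best) - pose$position)), 0.005 / 2 + 1e-12)
})

test_that("noiseless estimation is a fixed point at the truth and recovers
           it from an offset start", {
  pose <- magnet_pose(c(0.02, -0.01, 0.03),
                      heading_from_angles(45 * pi / 180, 10 * pi / 180))
  f <- frame_for(pose)
  at_truth <- estimate_pose(f, basis, arr, sp, init = pose)
  expect_lt(at_truth$cost, 1e-28)
  expect_equal(at_truth$pose$position, pose$position, tolerance = 1e-12)
  off <- c(pose$position + c(0.010, 0.010, 0.005),
           45 * pi / 180 + 20 * pi / 180, 10 * pi / 180 + 10 * pi / 180)
  est <- estimate_pose(f, basis, arr, sp, init = off)
  expect_true(est$converged)
  expect_lt(1e3 * sqrt(sum((est$pose$position - pose$position)^2)), 0.01)
  expect_lt(180 / pi * acos(min(1, sum(est$pose$heading * pose$heading))),
            0.01)
})

test_that("estimation agrees with an independent Levenberg-Marquardt
           implementation", {
  skip_if_not_installed("minpack.lm")
  pose <- magnet_pose(c(-0.012, 0.018, 0.027), heading_from_angles(2.1, -0.4))
  f <- frame_for(pose, sigma = 5e-5, seed = 99, quantize = TRUE)
  hm <- compensate(f, basis)
  start <- c(-0.005, 0.01, 0.03, 1.8, -0.2)
  ours <- estimate_pose(f, basis, arr, sp, init = start)
  ref <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) hm - capsnav:::dipole_z_model(p, arr$positions,
                                                   sp)$model,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  expect_equal(ours$pose$position, ref$par[1:3], tolerance = 1e-6)
  expect_equal(ours$cost, sum(ref$fvec^2), tolerance = 1e-6)
})

test_that("heading polarity is observable and roll is irrelevant", {
  pose <- magnet_pose(c(0.01, 0.01, 0.03), heading_from_angles(0.7, 0.3))
  f <- frame_for(pose)
  flipped <- magnet_pose(pose$position, -pose$heading)
  ff <- frame_for(flipped)
  # flipping the heading negates every reading -> distinguishable
  expect_equal(ff$readings, -f$readings, tolerance = 1e-15)
  est <- estimate_pose(f, basis, arr, sp, init = pose)
  expect_gt(sum(est$pose$heading * pose$heading), 0.999)
})

test_that("pose error after compensation matches the zero-current case", {
  set.seed(17)
  for (rep in 1:5) {
    pose <- magnet_pose(c(runif(1, -0.03, 0.03), runif(1, -0.03, 0.03),
                          runif(1, 0.015, 0.04)),
                        heading_from_angles(runif(1, -pi, pi),
                                            runif(1, -1, 1)))
    f_quiet <- frame_for(pose)
    f_loud <- frame_for(pose, currents = runif(10, -10, 10))
    e_quiet <- estimate_pose(f_quiet, basis, arr, sp)
    e_loud <- estimate_pose(f_loud, basis, arr, sp)
    err_q <- sqrt(sum((e_quiet$pose$position - pose$position)^2))
    err_l <- sqrt(sum((e_loud$pose$position - pose$position)^2))
    # noiseless: both are at numerical-convergence level; compare on a
    # 5 % relative scale with an absolute floor of 1 nm
    expect_lt(abs(err_l - err_q), 0.05 * max(err_q, 1e-9))
  }
})

test_that("estimation error decreases monotonically as noise shrinks", {
  sigmas <- c(1e-4, 1e-5, 1e-6) # 0.1, 0.01, 0.001 mT
  set.seed(23)
  poses <- lapply(1:15, function(i) {
    magnet_pose(c(runif(1, -0.04, 0.04), runif(1, -0.04, 0.04),
                  runif(1, 0.01, 0.04)),
                heading_from_angles(runif(1, -pi, pi), runif(1, -1.2, 1.2)))
  })
  med <- sapply(sigmas, function(s) {
    errs <- sapply(poses, function(po) {
      f <- synth_sensor_frame(capsule_state(po), rep(0, 10), arr, sp, basis,
                              noise_sigma = s, quantize = TRUE)
      est <- estimate_pose(f, basis, arr, sp, init = po)
      sqrt(sum((est$pose$position - po$position)^2))
    })
    median(errs)
  })
  expect_true(all(diff(med) < 0))
})

test_that("saturated sensors are dropped and an all-saturated frame errors", {
  pose <- magnet_pose(c(0, 0, 0.025), c(0, 0, 1))
  f <- frame_for(pose)
  f$saturated[1:31] <- TRUE
  expect_error(estimate_pose(f, basis, arr, sp, init = pose), "at least 6")
  f$saturated <- rep(FALSE, 36)
  f$saturated[1:3] <- TRUE
  expect_message(est <- estimate_pose(f, basis, arr, sp, init = pose),
                 "saturated")
  expect_equal(est$n_sensors_used, 33L)
})

test_that("tidy and glance summarize a pose estimate", {
  pose <- magnet_pose(c(0.01, 0, 0.03), c(1, 0, 0))
  est <- estimate_pose(frame_for(pose, sigma = 5e-5, seed = 2,
                                 quantize = TRUE), basis, arr, sp)
  td <- tidy(est)
  expect_equal(td$term, c("x", "y", "z", "yaw", "pitch"))
  expect_true(all(td$std.error >= 0))
  gl <- glance(est)
  expect_true(gl$converged)
  expect_equal(gl$n_sensors, 36L)
})
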