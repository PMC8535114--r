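#' Capsule state
#'
#' Pose, velocity and simulation time of the capsule in the quasi-static
#' plant.
#'
#' @param pose A [magnet_pose()].
#' @param velocity 3-vector, m/s.
#' @param time Seconds.
#' @return A `capsule_state` object.
#' @export
capsule_state <- function(pose, velocity = c(0, 0, 0), time = 0) {
  velocity <- check_vec3(velocity)
  structure(list(pose = pose, velocity = velocity, time = time),
            class = "capsule_state")
}

#' Simulation environment
#'
#' Overdamped mechanical surroundings of the capsule. In `free_space` the
#' capsule moves at terminal velocity `(|F| - friction) / drag` along the net
#' magnetic force; in `tube` mode motion is projected onto the tube
#' centerline and a friction threshold must be overcome before the capsule
#' moves at all.
#'
#' @param mode `"free_space"` or `"tube"`.
#' @param drag_coefficient Viscous drag, N s/m.
#' @param friction_threshold_force Minimum net force to initiate motion, N.
#' @param tube_centerline n x 3 matrix of polyline vertices (tube mode), m.
#' @param tube_radius Tube radius, m.
#' @return A `sim_environment` object.
#' @export
sim_environment <- function(mode = c("free_space", "tube"),
                            drag_coefficient = 3.5,
                            friction_threshold_force = 0,
                            tube_centerline = NULL, tube_radius = 0.008) {
  mode <- match.arg(mode)
  if (drag_coefficient <= 0) abort("`drag_coefficient` must be positive")
  if (mode == "tube" && (is.null(tube_centerline) ||
                         !is.matrix(tube_centerline) ||
                         nrow(tube_centerline) < 2L)) {
    abort("tube mode needs a `tube_centerline` polyline with >= 2 vertices")
  }
  structure(list(mode = mode, drag_coefficient = drag_coefficient,
                 friction_threshold_force = friction_threshold_force,
                 tube_centerline = tube_centerline, tube_radius = tube_radius),
            class = "sim_environment")
}

#' Synthesize one sensor frame
#'
#' Emulates a synchronized read of the Hall array: the dipole z-field of the
#' capsule magnet plus the superposed coil fields at the active currents,
#' additive Gaussian sensor noise, then the analog chain (range clipping and
#' ADC quantization). Bit-reproducible for a given `rng_seed`.
#'
#' @param state A [capsule_state()] (or a bare [magnet_pose()]).
#' @param currents Coil currents during the read, 10-vector A.
#' @param array A [sensor_array()].
#' @param spec A [magnet_spec()].
#' @param basis n_sensors x 10 unit-current basis ([sensor_basis_for()]).
#' @param noise_sigma Per-sensor field noise SD, Tesla (default 0.05 mT).
#' @param rng_seed Optional integer seed for the noise draw; when `NULL` the
#'   current RNG stream is used (as inside a seeded run).
#' @param quantize Apply the ADC quantization step (disable to study the
#'   ideal analog chain).
#' @return A [sensor_frame()] with saturation flags set by the analog model.
#' @export
synth_sensor_frame <- function(state, currents, array, spec, basis,
                               noise_sigma = 5e-5, rng_seed = NULL,
                               quantize = TRUE) {
  pose <- if (inherits(state, "capsule_state")) state$pose else state
  tstamp <- if (inherits(state, "capsule_state")) state$time else 0
  if (!is.null(rng_seed)) set.seed(rng_seed)
  b_true <- dipole_field_z(pose, spec, array$positions) +
    as.numeric(basis %*% currents)
  b_noisy <- b_true + if (noise_sigma > 0) {
    rnorm(length(b_true), 0, noise_sigma)
  } else 0
  v <- voltage_from_field(b_noisy, array)
  saturated <- attr(v, "saturated")
  v_q <- if (quantize) {
    lsb <- array$supply_voltage / 2^array$adc_bits
    round(as.numeric(v) / lsb) * lsb
  } else as.numeric(v)
  sensor_frame(field_from_voltage(v_q, array), currents, timestamp = tstamp,
               saturated = saturated)
}

## rotate heading toward `target_dir` by fraction f of the angle between them
relax_heading <- function(heading, target_dir, f) {
  t <- unitize(target_dir)
  d <- sum(heading * t)
  ax <- cross3(heading, t)
  s <- vnorm(ax)
  ang <- atan2(s, d)
  if (ang < 1e-12) return(heading)
  if (s < 1e-12) { # antiparallel: pick any perpendicular rotation axis
    seed <- if (abs(heading[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unitize(cross3(heading, seed))
  } else {
    ax <- ax / s
  }
  th <- f * ang
  # Rodrigues rotation about ax by th
  unitize(heading * cos(th) + cross3(ax, heading) * sin(th) +
            ax * sum(ax * heading) * (1 - cos(th)))
}

## nearest point on a polyline; returns point, tangent, arc position, distance
project_on_polyline <- function(p, poly, use_xy = FALSE) {
  q <- if (use_xy) p[1:2] else p
  best <- list(dist = Inf)
  s0 <- 0
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    av <- if (use_xy) a[1:2] else a
    bv <- if (use_xy) b[1:2] else b
    d <- bv - av
    len2 <- sum(d * d)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((q - av) * d) / len2))
    cp <- av + t * d
    dist <- sqrt(sum((q - cp)^2))
    seg_len <- sqrt(sum((poly[i + 1L, ] - poly[i, ])^2))
    if (dist < best$dist) {
      best <- list(dist = dist, s = s0 + t * seg_len,
                   point = poly[i, ] + t * (poly[i + 1L, ] - poly[i, ]),
                   tangent = unitize(poly[i + 1L, ] - poly[i, ]))
    }
    s0 <- s0 + seg_len
  }
  best$total <- s0
  best
}

## point on the polyline at arc position s (clamped)
polyline_at <- function(poly, s) {
  s <- max(0, s)
  for (i in seq_len(nrow(poly) - 1L)) {
    seg <- poly[i + 1L, ] - poly[i, ]
    len <- sqrt(sum(seg * seg))
    if (s <= len || i == nrow(poly) - 1L) {
      t <- if (len == 0) 0 else min(1, s / len)
      return(poly[i, ] + t * seg)
    }
    s <- s - len
  }
  poly[nrow(poly), ]
}

#' Advance the capsule one time step
#'
#' Quasi-static (inertia-free) plant update. The heading relaxes toward the
#' local field direction with first-order time constant `tau_align`
#' (magnetic torque synchronizes the capsule with the field); translation is
#' at overdamped terminal velocity
#' `v = max(0, (|F_net| - friction) / drag)` along the net magnetic force,
#' projected onto the tube centerline in tube mode.
#'
#' @param state A [capsule_state()].
#' @param currents Coil currents, 10-vector A.
#' @param env A [sim_environment()].
#' @param config An [ema_config()].
#' @param spec A [magnet_spec()].
#' @param dt Time step, s, in (0, 0.1].
#' @param tau_align Heading alignment time constant at the reference field
#'   `b_ref`, s. The torque scales with the field, so the effective rate is
#'   `|B| / (b_ref * tau_align)`: halving the applied field doubles the
#'   alignment time.
#' @param b_ref Reference field for `tau_align`, Tesla (default 5 mT, the
#'   free-space preset).
#' @return The updated [capsule_state()].
#' @export
step_dynamics <- function(state, currents, env, config, spec, dt,
                          tau_align = 0.05, b_ref = 5e-3) {
  if (!(dt > 0 && dt <= 0.1)) abort("`dt` must be in (0, 0.1] s")
  pose <- state$pose
  heading <- pose$heading
  pos <- pose$position
  if (any(currents != 0)) {
    B <- ema_field(config, currents, pos)
    bmag <- vnorm(B)
    if (bmag > 1e-12) {
      rate <- bmag / (b_ref * tau_align)
      heading <- relax_heading(heading, B, 1 - exp(-dt * rate))
    }
    G <- field_gradient_tensor(config, currents, pos)
    Fm <- magnetic_force(spec, heading, G)
  } else {
    Fm <- c(0, 0, 0)
  }
  fmag <- vnorm(Fm)
  v <- c(0, 0, 0)
  if (fmag > env$friction_threshold_force && fmag > 0) {
    speed <- (fmag - env$friction_threshold_force) / env$drag_coefficient
    v <- speed * Fm / fmag
    if (env$mode == "tube") {
      pr <- project_on_polyline(pos, env$tube_centerline)
      v <- sum(v * pr$tangent) * pr$tangent
    }
  }
  new_pos <- pos + v * dt
  if (env$mode == "tube") { # confine to the tube
    pr <- project_on_polyline(new_pos, env$tube_centerline)
    if (pr$dist > env$tube_radius) {
      new_pos <- pr$point + (new_pos - pr$point) * env$tube_radius / pr$dist
    }
  }
  capsule_state(magnet_pose(new_pos, heading, normalize = TRUE),
                velocity = v, time = state$time + dt)
}

#' U-shaped desired path
#'
#' Polyline with two parallel straight legs joined by a semicircular turn,
#' the trajectory family of the free-space tracking trial. The path fits in
#' an `extent` x `gap + spacing` bounding box at height `z`.
#'
#' @param extent Overall length along x, m (default 80 mm).
#' @param spacing Waypoint spacing, m.
#' @param gap Separation between the legs (= turn diameter), m.
#' @param z Path height above the sensor board, m (default the ROI centre
#'   plane, where the coil system is best conditioned).
#' @return n x 3 matrix of waypoints; attribute `"arc_length"` holds the
#'   ideal length `2 * leg + pi * radius`.
#' @export
generate_ushape_path <- function(extent = 0.08, spacing = 0.005, gap = 0.04,
                                 z = 0.025) {
  radius <- gap / 2
  if (extent <= radius) abort("`extent` must exceed the turn radius")
  x_left <- -extent / 2
  x_right <- extent / 2 - radius
  leg <- x_right - x_left
  p1 <- cbind(seq(x_left, x_right, by = spacing), -radius, z)
  ang <- seq(-pi / 2, pi / 2, by = spacing / radius)
  arc <- cbind(x_right + radius * cos(ang), radius * sin(ang), z)
  p2 <- cbind(seq(x_right, x_left, by = -spacing), radius, z)
  path <- rbind(p1, arc, p2)
  dimnames(path) <- NULL
  # drop consecutive duplicates at the joins
  keep <- c(TRUE, rowSums(abs(diff(path))) > 1e-12)
  path <- path[keep, , drop = FALSE]
  attr(path, "arc_length") <- 2 * leg + pi * radius
  path
}

#' Run the closed control loop
#'
#' The in-silico twin of a remotely driven tracking trial. At each 20 Hz
#' tick the loop estimates the capsule pose from the latest sensor frame,
#' steers toward the desired path (path-tangent pursuit with cross-track
#' error feedback stands in for a human joystick operator), maps the
#' yaw/pitch/push command to a desired wrench, allocates coil currents by
#' pseudoinverse, advances the plant, and synthesizes the next frame.
#'
#' @param path n x 3 waypoint matrix (>= 2 rows) inside the ROI.
#' @param env A [sim_environment()].
#' @param config An [ema_config()].
#' @param array A [sensor_array()].
#' @param spec A [magnet_spec()].
#' @param controller List of controls: `F` push magnitude (T/m, default 0.05,
#'   the 50 mT/m free-space preset), `gamma` field:gradient ratio (m, default
#'   0.1), `dt` (s, default 0.05), `lookahead` (m), `k_crosstrack`,
#'   `capture_radius` (m, default 0.005), `max_steps`, `noise_sigma` (T,
#'   default 5e-5), `tau_align` (s), `planar` (hold the pitch command at
#'   zero; default auto-detects a planar path), `sv_cutoff` (allocation
#'   pseudoinverse truncation, default 1e-3).
#' @param seed Integer seed; the run is bit-reproducible from (inputs, seed).
#' @return A `capsnav_trajectory` tibble, one row per tick: time, commands,
#'   currents `i1..i10`, true and estimated pose, localization and
#'   path-tracking errors (3D and in-plane). Attributes: `summary` (list of
#'   error statistics, in mm), `seed`, `path`.
#' @export
run_closed_loop <- function(path, env, config, array, spec,
                            controller = list(), seed = 1L) {
  if (!is.matrix(path) || nrow(path) < 2L) abort("`path` needs >= 2 waypoints")
  for (i in seq_len(nrow(path))) {
    if (!in_roi(config$roi, path[i, ])) {
      abort(sprintf("waypoint %d is outside the ROI", i))
    }
  }
  ctl <- modifyList(list(F = 0.05, gamma = 0.1, dt = 0.05, lookahead = 0.004,
                         k_crosstrack = 3, capture_radius = 0.005,
                         max_steps = 600L, noise_sigma = 5e-5,
                         tau_align = 0.05, planar = NULL,
                         sv_cutoff = 1e-3),
                    controller)
  # On a planar path the pitch command is held at zero: a force request with
  # all three heading components nonzero is ill-conditioned near the coil
  # symmetry planes (trace-free gradient), so out-of-plane corrections would
  # demand clamped currents for micrometre z errors.
  if (is.null(ctl$planar)) ctl$planar <- diff(range(path[, 3])) < 1e-9
  set.seed(seed)
  basis <- sensor_basis_for(config, array)

  start_dir <- unitize(path[2, ] - path[1, ])
  state <- capsule_state(magnet_pose(path[1, ], start_dir, normalize = TRUE))
  frame <- synth_sensor_frame(state, rep(0, 10), array, spec, basis,
                              noise_sigma = ctl$noise_sigma)
  est <- estimate_pose(frame, basis, array, spec, roi = config$roi)

  rows <- vector("list", ctl$max_steps)
  n_bad <- 0L
  aborted <- FALSE
  total_len <- project_on_polyline(path[1, ], path)$total
  for (step in seq_len(ctl$max_steps)) {
    p_est <- est$pose$position
    pr <- project_on_polyline(p_est, path)
    if (pr$s >= total_len - 1e-9 ||
        vnorm(p_est - path[nrow(path), ]) < ctl$capture_radius) break
    target <- polyline_at(path, pr$s + ctl$lookahead)
    aim <- (target - p_est) + ctl$k_crosstrack * (pr$point - p_est)
    if (ctl$planar) aim[3] <- 0
    if (vnorm(aim) < 1e-9) aim <- pr$tangent
    u <- unitize(aim)
    yaw <- atan2(u[2], u[1])
    pitch <- if (ctl$planar) 0 else asin(max(-1, min(1, u[3])))
    wrench <- command_to_desired(yaw, pitch, ctl$F, ctl$gamma)
    X <- build_actuation_matrix(config, clamp_to_roi(config$roi, p_est),
                                heading_from_angles(yaw, pitch))
    currents <- suppressWarnings(
      allocate_currents(X, wrench, sv_cutoff = ctl$sv_cutoff))
    clamped <- any(abs(currents) > config$current_limit)
    currents <- pmax(-config$current_limit,
                     pmin(config$current_limit, currents))

    state <- step_dynamics(state, currents, env, config, spec, ctl$dt,
                           tau_align = ctl$tau_align)
    frame <- synth_sensor_frame(state, currents, array, spec, basis,
                                noise_sigma = ctl$noise_sigma)
    est_new <- tryCatch(
      estimate_pose(frame, basis, array, spec, init = est, roi = config$roi),
      error = function(e) NULL)
    if (is.null(est_new) || !est_new$converged) {
      n_bad <- n_bad + 1L
      if (n_bad > 10L) { aborted <- TRUE; break }
    } else {
      n_bad <- 0L
    }
    if (!is.null(est_new)) est <- est_new

    tp <- state$pose$position
    ta <- angles_from_heading(state$pose$heading)
    err_path <- project_on_polyline(tp, path)$dist
    err_path_xy <- project_on_polyline(tp, path, use_xy = TRUE)$dist
    rows[[step]] <- tibble::tibble(
      time = state$time, cmd_yaw = yaw, cmd_pitch = pitch, cmd_F = ctl$F,
      !!!setNames(as.list(currents), paste0("i", 1:10)),
      clamped = clamped,
      x = tp[1], y = tp[2], z = tp[3],
      yaw = ta[["yaw"]], pitch = ta[["pitch"]],
      est_x = est$pose$position[1], est_y = est$pose$position[2],
      est_z = est$pose$position[3], est_yaw = est$yaw,
      est_pitch = est$pitch, est_cost = est$cost,
      converged = est$converged,
      loc_error = vnorm(tp - est$pose$position),
      path_error = err_path, path_error_xy = err_path_xy
    )
  }
  log <- dplyr::bind_rows(rows)
  summary <- trajectory_summary(log)
  summary$aborted <- aborted
  structure(log, class = c("capsnav_trajectory", class(log)),
            summary = summary, seed = seed, path = path,
            controller = ctl)
}

clamp_to_roi <- function(roi, p) {
  c(max(roi$xlim[1], min(roi$xlim[2], p[1])),
    max(roi$ylim[1], min(roi$ylim[2], p[2])),
    max(roi$zlim[1], min(roi$zlim[2], p[3])))
}

trajectory_summary <- function(log) {
  mm <- function(x) 1e3 * x
  list(
    n_steps = nrow(log),
    mean_error_mm = mm(mean(log$path_error_xy)),
    sd_error_mm = mm(sd(log$path_error_xy)),
    max_error_mm = mm(max(log$path_error_xy)),
    mean_error_3d_mm = mm(mean(log$path_error)),
    mean_loc_error_mm = mm(mean(log$loc_error)),
    max_loc_error_mm = mm(max(log$loc_error))
  )
}

#' @export
print.capsnav_trajectory <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "<capsnav_trajectory> %d ticks (seed %s)\n  path error (xy): mean %.3f mm, SD %.3f mm, max %.3f mm\n  localization error: mean %.4f mm, max %.4f mm\n",
    s$n_steps, format(attr(x, "seed")), s$mean_error_mm, s$sd_error_mm,
    s$max_error_mm, s$mean_loc_error_mm, s$max_loc_error_mm))
  NextMethod()
}

#' @rdname run_closed_loop
#' @param x A `capsnav_trajectory`.
#' @param ... Unused.
#' @return `glance()`: one-row tibble of the summary statistics (mm).
#' @method glance capsnav_trajectory
#' @export
glance.capsnav_trajectory <- function(x, ...) {
  s <- attr(x, "summary")
  tibble::tibble(n_steps = s$n_steps, mean_error_mm = s$mean_error_mm,
                 sd_error_mm = s$sd_error_mm, max_error_mm = s$max_error_mm,
                 mean_loc_error_mm = s$mean_loc_error_mm,
                 seed = attr(x, "seed"), aborted = isTRUE(s$aborted))
}
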