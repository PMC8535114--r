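#' External-field compensation
#'
#' Removes the actuation system's contribution from a sensor frame by
#' subtracting the unit-current basis fields weighted by the currents active
#' at read time: `HM = HS - sum_k H_k i_k`. When the frame was synthesized
#' with the same basis the cancellation is exact to machine precision; no
#' coil geometry enters beyond the basis table itself.
#'
#' @param frame A [sensor_frame()].
#' @param basis n_sensors x 10 matrix of unit-current fields along the sensor
#'   axis (T/A), e.g. from [sensor_basis_for()].
#' @return Numeric vector of compensated per-sensor fields `HM`, Tesla.
#' @export
compensate <- function(frame, basis) {
  if (!is.matrix(basis) || ncol(basis) != 10L) {
    abort("`basis` must be an n_sensors x 10 matrix")
  }
  if (nrow(basis) != length(frame$readings)) {
    abort(sprintf("basis covers %d sensors but the frame has %d readings",
                  nrow(basis), length(frame$readings)))
  }
  frame$readings - as.numeric(basis %*% frame$currents)
}

#' Unit-current basis at the sensor positions
#'
#' Convenience wrapper building the n_sensors x 10 z-component basis matrix
#' used by [compensate()] and the frame synthesizer.
#'
#' @param config An [ema_config()].
#' @param array A [sensor_array()].
#' @return n_sensors x 10 numeric matrix, T/A.
#' @export
sensor_basis_for <- function(config, array) {
  sensor_basis_matrix(config, array)
}

## model z-fields and (optionally) the Jacobian wrt (a, b, c, yaw, pitch)
## at sensor matrix S; vectorized over sensors
dipole_z_model <- function(params, S, spec, jacobian = FALSE) {
  pos <- params[1:3]
  yaw <- params[4]; pitch <- params[5]
  cp <- cos(pitch); sp <- sin(pitch); cy <- cos(yaw); sy <- sin(yaw)
  D <- c(cp * cy, cp * sy, sp)
  BT <- spec$dipole_strength
  P <- sweep(S, 2, pos)
  r2 <- rowSums(P * P)
  r <- sqrt(r2)
  r3 <- r2 * r; r5 <- r2 * r3; r7 <- r2 * r5
  c1 <- P %*% D
  c1 <- c1[, 1]
  model <- BT * (3 * c1 * P[, 3] / r5 - D[3] / r3)
  if (!jacobian) return(list(model = model))
  J <- matrix(0, nrow(S), 5L)
  for (j in 1:3) {
    dz <- if (j == 3) 1 else 0
    J[, j] <- BT * (-3 * D[j] * P[, 3] / r5 - 3 * c1 * dz / r5 +
                      15 * c1 * P[, 3] * P[, j] / r7 - 3 * D[3] * P[, j] / r5)
  }
  dmodel_dD <- cbind(BT * 3 * P[, 1] * P[, 3] / r5,
                     BT * 3 * P[, 2] * P[, 3] / r5,
                     BT * (3 * P[, 3] * P[, 3] / r5 - 1 / r3))
  dD_dyaw <- c(-cp * sy, cp * cy, 0)
  dD_dpitch <- c(-sp * cy, -sp * sy, cp)
  J[, 4] <- dmodel_dD %*% dD_dyaw
  J[, 5] <- dmodel_dD %*% dD_dpitch
  list(model = model, jacobian = J)
}

#' Residuals of the dipole measurement model
#'
#' For candidate parameters `(a, b, c, yaw, pitch)`, the per-sensor residual
#' `measured - model` where the model is the point-dipole z-field at each
#' sensor. The squared-residual sum is the cost the estimator minimizes.
#'
#' @param params Numeric 5-vector `(a, b, c, yaw, pitch)`, metres/radians.
#' @param measurements Compensated per-sensor fields `HM`, Tesla.
#' @param array A [sensor_array()].
#' @param spec A [magnet_spec()].
#' @return Residual vector (T) with attribute `cost` (sum of squares).
#' @export
pose_residuals <- function(params, measurements, array, spec) {
  if (params[3] < array$positions[1, 3] + 0.005) {
    abort("candidate position must be at least 5 mm above the sensor plane")
  }
  m <- dipole_z_model(params, array$positions, spec)
  r <- measurements - m$model
  attr(r, "cost") <- sum(r * r)
  r
}

## coarse grid search over the ROI x 14 candidate headings (axis-aligned plus
## body-diagonal); returns the `k` lowest-cost (position, heading) candidates
cold_start_search <- function(measurements, array, spec, roi,
                              grid_pitch = 0.010, k = 3L) {
  z_floor <- array$positions[1, 3] + 0.005
  xs <- seq(roi$xlim[1], roi$xlim[2], by = grid_pitch)
  ys <- seq(roi$ylim[1], roi$ylim[2], by = grid_pitch)
  zs <- seq(max(roi$zlim[1], z_floor), roi$zlim[2], by = grid_pitch)
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  p4 <- pi / 4
  headings <- c(
    list(c(0, 0), c(pi / 2, 0), c(pi, 0), c(-pi / 2, 0),
         c(0, pi / 2), c(0, -pi / 2)),
    lapply(seq(0, 3), function(q) c(-pi + p4 + q * pi / 2, asin(1 / sqrt(3)))),
    lapply(seq(0, 3), function(q) c(-pi + p4 + q * pi / 2, -asin(1 / sqrt(3))))
  )
  S <- array$positions
  BT <- spec$dipole_strength
  Px <- outer(S[, 1], g[, 1], "-")
  Py <- outer(S[, 2], g[, 2], "-")
  Pz <- outer(S[, 3], g[, 3], "-")
  r2 <- Px^2 + Py^2 + Pz^2
  r <- sqrt(r2); r3 <- r2 * r; r5 <- r2 * r3
  cands <- list()
  for (hp in headings) {
    D <- heading_from_angles(hp[1], hp[2])
    c1 <- D[1] * Px + D[2] * Py + D[3] * Pz
    model <- BT * (3 * c1 * Pz / r5 - D[3] / r3)
    cost <- colSums((measurements - model)^2)
    i <- which.min(cost)
    cands[[length(cands) + 1L]] <- list(cost = cost[i],
                                        params = unname(c(g[i, ], hp)))
  }
  cands <- cands[order(vapply(cands, `[[`, numeric(1), "cost"))]
  lapply(cands[seq_len(min(k, length(cands)))], `[[`, "params")
}

## damped Gauss-Newton (Levenberg-Marquardt) refinement of one start point;
## Marquardt diagonal scaling, multiplicative x10 / /10 damping schedule,
## z clamped to the floor (capsule cannot be below the board)
lm_refine <- function(params, meas, S, spec, opt) {
  params[3] <- max(params[3], opt$z_floor)
  mj <- dipole_z_model(params, S, spec, jacobian = TRUE)
  res <- meas - mj$model
  cost <- sum(res * res)
  lambda <- opt$lambda0
  converged <- FALSE
  iter <- 0L
  while (iter < opt$max_iter) {
    iter <- iter + 1L
    J <- -mj$jacobian # residual = meas - model
    JtJ <- crossprod(J)
    g <- crossprod(J, res)
    step_ok <- FALSE
    for (inner in 1:50) {
      A <- JtJ + lambda * diag(diag(JtJ), 5L)
      delta <- tryCatch(-solve(A, g)[, 1], error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- params + delta
        cand[3] <- max(cand[3], opt$z_floor)
        m2 <- dipole_z_model(cand, S, spec, jacobian = TRUE)
        r2 <- meas - m2$model
        c2 <- sum(r2 * r2)
        if (is.finite(c2) && c2 <= cost) {
          rel_drop <- if (cost > 0) (cost - c2) / cost else 0
          step_norm <- vnorm(params - cand)
          params <- cand; res <- r2; mj <- m2
          step_ok <- TRUE
          # the cost criterion only counts when the damping is relaxed: a
          # microscopic forced step under heavy damping is not convergence
          if (step_norm < opt$step_tol || c2 == 0 ||
              (rel_drop < opt$cost_tol && lambda <= opt$lambda0)) {
            converged <- TRUE
          }
          lambda <- max(lambda / 10, 1e-12)
          cost <- c2
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!step_ok) {
      converged <- TRUE # no downhill step exists: stalled at a minimum
      break
    }
    if (converged) break
  }
  list(params = params, cost = cost, iterations = iter,
       converged = converged, jacobian = mj$jacobian)
}

#' Estimate the capsule pose from a sensor frame
#'
#' The full 5-DOF estimation pipeline: compensate the actuation field
#' ([compensate()]), drop saturated sensors, and minimize the squared
#' z-field residual over `(a, b, c, yaw, pitch)` with a damped Gauss-Newton
#' (Levenberg-Marquardt) iteration using the analytic Jacobian of the dipole
#' model. Roll about the magnetization axis is unobservable and excluded by
#' the parameterization; heading polarity is observable (flipping the heading
#' negates every reading).
#'
#' Initialization: a `magnet_pose` or previous `pose_estimate` (`init`) warm
#' starts the solver; otherwise a coarse grid search over the ROI (10 mm
#' pitch, six axis-aligned headings) picks the lowest-cost cell.
#'
#' @param frame A [sensor_frame()].
#' @param basis n_sensors x 10 unit-current basis matrix ([sensor_basis_for()]).
#' @param array A [sensor_array()].
#' @param spec A [magnet_spec()].
#' @param init Optional warm start: `magnet_pose`, `pose_estimate`, or a
#'   numeric 5-vector `(a, b, c, yaw, pitch)`.
#' @param roi ROI list used by the cold-start grid (defaults to the standard
#'   100 x 100 x 40 mm box when `NULL`).
#' @param options List overriding solver controls: `max_iter` (200),
#'   `step_tol` (1e-10), `cost_tol` (1e-12), `lambda0` (1e-3), `z_floor`
#'   (5 mm above the board).
#' @return A `pose_estimate`: fields `pose` ([magnet_pose()]), `yaw`, `pitch`
#'   (rad), `cost` (T^2), `iterations`, `converged`, `covariance` (5 x 5
#'   proxy from the final Jacobian), `n_sensors_used`.
#' @export
estimate_pose <- function(frame, basis, array, spec, init = NULL, roi = NULL,
                          options = list()) {
  opt <- modifyList(list(max_iter = 200L, step_tol = 1e-10, cost_tol = 1e-12,
                         lambda0 = 1e-3,
                         z_floor = array$positions[1, 3] + 0.005),
                    options)
  hm_all <- compensate(frame, basis)
  use <- !frame$saturated
  if (sum(use) < 6L) {
    abort(sprintf("only %d unsaturated sensors; at least 6 are required",
                  sum(use)))
  }
  if (any(!use)) {
    inform(sprintf("dropping %d saturated sensor(s) from the fit", sum(!use)))
  }
  meas <- hm_all[use]
  S <- array$positions[use, , drop = FALSE]
  sub_array <- array
  sub_array$positions <- S

  roi <- roi %||% list(xlim = c(-0.05, 0.05), ylim = c(-0.05, 0.05),
                       zlim = c(0.005, 0.045))
  starts <- if (is.null(init)) {
    cold_start_search(meas, sub_array, spec, roi)
  } else if (inherits(init, "pose_estimate")) {
    list(c(init$pose$position, init$yaw, init$pitch))
  } else if (inherits(init, "magnet_pose")) {
    ang <- angles_from_heading(init$heading)
    list(c(init$position, ang[["yaw"]], ang[["pitch"]]))
  } else {
    list(as.numeric(init))
  }

  fit <- NULL
  for (p0 in starts) {
    cand_fit <- lm_refine(p0, meas, S, spec, opt)
    if (is.null(fit) || cand_fit$cost < fit$cost) fit <- cand_fit
    if (fit$cost == 0) break
  }
  params <- fit$params
  cost <- fit$cost

  JtJ <- crossprod(fit$jacobian)
  covariance <- tryCatch(solve(JtJ), error = function(e) matrix(NA_real_, 5, 5))
  yaw <- atan2(sin(params[4]), cos(params[4]))
  pitch <- params[5]
  structure(
    list(pose = magnet_pose(params[1:3], heading_from_angles(yaw, pitch),
                            normalize = TRUE),
         yaw = yaw, pitch = pitch, cost = cost, iterations = fit$iterations,
         converged = fit$converged, covariance = covariance,
         n_sensors_used = sum(use)),
    class = "pose_estimate"
  )
}

#' @export
print.pose_estimate <- function(x, ...) {
  cat(sprintf(
    "<pose_estimate> (%.2f, %.2f, %.2f) mm, yaw %.2f deg, pitch %.2f deg\n",
    1e3 * x$pose$position[1], 1e3 * x$pose$position[2],
    1e3 * x$pose$position[3], 180 / pi * x$yaw, 180 / pi * x$pitch))
  cat(sprintf("  cost %.3g T^2, %d iterations, converged: %s, %d sensors\n",
              x$cost, x$iterations, x$converged, x$n_sensors_used))
  invisible(x)
}

#' Tidy a pose estimate
#'
#' @param x A `pose_estimate`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter with `estimate` and a standard
#'   error proxy from the final-Jacobian covariance (scaled by the residual
#'   variance). `glance()`: one-row fit summary.
#' @method tidy pose_estimate
#' @export
tidy.pose_estimate <- function(x, ...) {
  est <- c(x$pose$position, x$yaw, x$pitch)
  dof <- max(1L, x$n_sensors_used - 5L)
  sigma2 <- x$cost / dof
  se <- sqrt(pmax(0, diag(x$covariance)) * sigma2)
  tibble::tibble(
    term = c("x", "y", "z", "yaw", "pitch"),
    estimate = est,
    std.error = se,
    unit = c("m", "m", "m", "rad", "rad")
  )
}

#' @rdname tidy.pose_estimate
#' @method glance pose_estimate
#' @export
glance.pose_estimate <- function(x, ...) {
  tibble::tibble(cost = x$cost, iterations = x$iterations,
                 converged = x$converged, n_sensors = x$n_sensors_used)
}
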