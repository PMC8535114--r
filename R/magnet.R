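#' Capsule magnet specification
#'
#' Describes the axially magnetized permanent magnet carried by the capsule as
#' a point dipole. The dipole strength `BT = mu0 * |moment| / (4 pi)` is the
#' single constant that scales every field the magnet produces.
#'
#' Either give `volume` directly or give the cylinder `diameter` and `length`;
#' either give `magnetization` (A/m) or the `remanence` (T), from which
#' `magnetization = remanence / mu0`.
#'
#' @param diameter,length Cylinder dimensions in metres. Defaults describe a
#'   10 mm x 12 mm NdFeB magnet.
#' @param volume Magnet volume in cubic metres; overrides `diameter`/`length`.
#' @param remanence Remanent flux density in Tesla (default 1.48, typical for
#'   an N54 grade).
#' @param magnetization Magnetization magnitude in A/m; overrides `remanence`.
#' @return An object of class `magnet_spec` with fields `volume` (m^3),
#'   `magnetization` (A/m), `moment` (A m^2) and `dipole_strength`
#'   (`BT`, T m^3).
#' @examples
#' spec <- magnet_spec()
#' spec$dipole_strength # ~1.11e-7 T m^3
#' @export
magnet_spec <- function(diameter = 0.010, length = 0.012, volume = NULL,
                        remanence = 1.48, magnetization = NULL) {
  volume <- volume %||% (pi * (diameter / 2)^2 * length)
  magnetization <- magnetization %||% (remanence / MU0)
  if (volume <= 0 || magnetization <= 0) {
    abort("magnet volume and magnetization must be strictly positive")
  }
  moment <- volume * magnetization
  structure(
    list(volume = volume, magnetization = magnetization, moment = moment,
         dipole_strength = MU0 * moment / (4 * pi)),
    class = "magnet_spec"
  )
}

#' @export
print.magnet_spec <- function(x, ...) {
  cat("<magnet_spec>\n")
  cat(sprintf("  volume        %.4g m^3\n", x$volume))
  cat(sprintf("  magnetization %.4g A/m\n", x$magnetization))
  cat(sprintf("  moment        %.4g A m^2\n", x$moment))
  cat(sprintf("  BT            %.4g T m^3\n", x$dipole_strength))
  invisible(x)
}

#' Capsule magnet pose
#'
#' Position of the magnet centre and the unit heading of its magnetization
#' axis. Roll about the axis is unobservable for an axially magnetized magnet
#' and is not part of the pose.
#'
#' @param position Numeric 3-vector, metres.
#' @param heading Numeric 3-vector; normalized to unit length (must be within
#'   1e-9 of unit norm already, or pass `normalize = TRUE`).
#' @param normalize Normalize `heading` instead of insisting it is unit-norm.
#' @return An object of class `magnet_pose` with `position` and `heading`.
#' @export
magnet_pose <- function(position, heading, normalize = FALSE) {
  position <- check_vec3(position)
  heading <- check_vec3(heading)
  n <- vnorm(heading)
  if (normalize) {
    heading <- heading / n
  } else if (abs(n - 1) > 1e-9) {
    abort(sprintf("heading must be unit-norm (got |D| = %.12g)", n))
  }
  structure(list(position = position, heading = heading),
            class = "magnet_pose")
}

#' @export
print.magnet_pose <- function(x, ...) {
  yp <- angles_from_heading(x$heading)
  cat(sprintf("<magnet_pose> at (%.1f, %.1f, %.1f) mm, yaw %.1f deg, pitch %.1f deg\n",
              1e3 * x$position[1], 1e3 * x$position[2], 1e3 * x$position[3],
              180 / pi * yp[["yaw"]], 180 / pi * yp[["pitch"]]))
  invisible(x)
}

#' Point-dipole magnetic field
#'
#' Field of the capsule magnet at `point`, using the point-dipole model
#' `B = BT * (3 (D.P) P / |P|^5 - D / |P|^3)` with `P = point - position`.
#' Valid in the far field; evaluation closer than 1 mm to the dipole centre is
#' an error because the model diverges there.
#'
#' @param pose A [magnet_pose()].
#' @param spec A [magnet_spec()].
#' @param point Numeric 3-vector, metres.
#' @return Numeric 3-vector, Tesla.
#' @examples
#' sp <- magnet_spec()
#' po <- magnet_pose(c(0, 0, 0), c(0, 0, 1))
#' dipole_field(po, sp, c(0, 0, 0.05)) # on-axis: (0, 0, 2 BT / d^3)
#' @export
dipole_field <- function(pose, spec, point) {
  point <- check_vec3(point)
  P <- point - pose$position
  r <- vnorm(P)
  if (r < 1e-3) {
    abort(sprintf(
      "field requested %.3g mm from the dipole centre (point %s); the point-dipole model is invalid inside 1 mm",
      1e3 * r, paste(signif(point, 4), collapse = ", ")))
  }
  D <- pose$heading
  BT <- spec$dipole_strength
  BT * (3 * sum(D * P) * P / r^5 - D / r^3)
}

#' Dipole field z-component at sensor positions
#'
#' The board-normal component measured by the mono-axis Hall sensors:
#' `Bz = BT * (3 (D.P) Pz / |P|^5 - Dz / |P|^3)`. Vectorized over sensor
#' positions for the estimator's inner loop.
#'
#' @inheritParams dipole_field
#' @param sensors Numeric 3-vector or an n x 3 matrix of sensor positions (m).
#' @return Numeric scalar or length-n vector, Tesla.
#' @export
dipole_field_z <- function(pose, spec, sensors) {
  S <- if (is.matrix(sensors)) sensors else matrix(check_vec3(sensors), 1L)
  P <- sweep(S, 2, pose$position)
  r2 <- rowSums(P * P)
  r <- sqrt(r2)
  if (any(r < 1e-3)) {
    i <- which.min(r)
    abort(sprintf(
      "field requested %.3g mm from the dipole centre (sensor %s); the point-dipole model is invalid inside 1 mm",
      1e3 * r[i], paste(signif(S[i, ], 4), collapse = ", ")))
  }
  D <- pose$heading
  BT <- spec$dipole_strength
  dp <- P %*% D
  out <- BT * (3 * dp[, 1] * P[, 3] / (r2 * r2 * r) - D[3] / (r2 * r))
  if (is.matrix(sensors)) out else out[[1]]
}

#' Magnetic torque on the capsule magnet
#'
#' `tau = V (M x B)` with `M = magnetization * heading`. The torque is
#' perpendicular to both the heading and the field and vanishes when they are
#' aligned; it is what steers the capsule toward the applied field direction.
#'
#' @inheritParams dipole_field
#' @param heading Unit 3-vector, the magnetization direction.
#' @param B Applied field, 3-vector Tesla.
#' @return Torque 3-vector, N m.
#' @export
magnetic_torque <- function(spec, heading, B) {
  heading <- check_vec3(heading)
  B <- check_vec3(B)
  spec$volume * spec$magnetization * cross3(heading, B)
}

#' Magnetic force on the capsule magnet
#'
#' `F = V (M . grad) B`: component j is `V |M| * sum_i heading_i dB_j/dx_i`.
#' Uniform fields exert no force; propulsion requires a gradient.
#'
#' @inheritParams magnetic_torque
#' @param gradB 3x3 gradient tensor, `gradB[i, j] = dB_i / dx_j`, T/m.
#' @return Force 3-vector, Newton.
#' @export
magnetic_force <- function(spec, heading, gradB) {
  heading <- check_vec3(heading)
  if (!is.matrix(gradB) || !all(dim(gradB) == c(3L, 3L)) || !all(is.finite(gradB))) {
    abort("`gradB` must be a finite 3x3 matrix")
  }
  spec$volume * spec$magnetization * as.numeric(gradB %*% heading)
}

#' Heading angles
#'
#' Convert between a unit heading vector and yaw/pitch angles. Yaw is measured
#' from +x about +z; pitch is elevation from the xy-plane:
#' `D = (cos p cos y, cos p sin y, sin p)`.
#'
#' At pitch +/-90 degrees yaw is undefined (gimbal degeneracy);
#' `angles_from_heading()` returns yaw 0 there and sets the `"degenerate"`
#' attribute.
#'
#' @param yaw,pitch Angles in radians.
#' @param D Unit heading 3-vector.
#' @return `heading_from_angles()`: unit 3-vector. `angles_from_heading()`:
#'   named numeric vector `c(yaw =, pitch =)` in radians.
#' @examples
#' heading_from_angles(pi / 2, 0) # (0, 1, 0)
#' angles_from_heading(c(0, 0, 1)) # pitch pi/2, yaw 0 by convention
#' @export
heading_from_angles <- function(yaw, pitch) {
  c(cos(pitch) * cos(yaw), cos(pitch) * sin(yaw), sin(pitch))
}

#' @rdname heading_from_angles
#' @export
angles_from_heading <- function(D) {
  D <- check_vec3(D)
  if (abs(D[3]) > 1 + 1e-12) abort("|Dz| must be <= 1 for a unit heading")
  pitch <- asin(max(-1, min(1, D[3])))
  hypot <- sqrt(D[1]^2 + D[2]^2)
  if (hypot < 1e-12) {
    out <- c(yaw = 0, pitch = pitch)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  c(yaw = atan2(D[2], D[1]), pitch = pitch)
}
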