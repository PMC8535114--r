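#' Coil specification
#'
#' One electromagnet channel, modelled as an air-core filament loop (circular)
#' or a single rectangular filament loop, multiplied by its turn count. The
#' field direction follows the right-hand rule about `axis`, so an opposed
#' pair (Maxwell/anti-Helmholtz) is written as two coils with antiparallel
#' axes.
#'
#' @param shape `"circular"` or `"rectangular"`.
#' @param center Coil centre, 3-vector metres.
#' @param axis Coil axis, normalized internally.
#' @param radius Loop radius (circular), metres.
#' @param half_width,half_height Rectangle half-sides (rectangular), metres.
#' @param turns Positive integer turn count.
#' @param label Channel label.
#' @return A `coil_spec` object.
#' @export
coil_spec <- function(shape = c("circular", "rectangular"), center, axis,
                      radius = NULL, half_width = NULL, half_height = NULL,
                      turns = 1L, label = "") {
  shape <- match.arg(shape)
  center <- check_vec3(center)
  axis <- unitize(check_vec3(axis))
  if (turns < 1) abort("`turns` must be a positive integer")
  if (shape == "circular") {
    if (is.null(radius) || radius <= 0) abort("circular coil needs a positive `radius`")
  } else {
    if (is.null(half_width) || is.null(half_height) ||
        half_width <= 0 || half_height <= 0) {
      abort("rectangular coil needs positive `half_width` and `half_height`")
    }
  }
  structure(
    list(shape = shape, center = center, axis = axis, radius = radius,
         half_width = half_width, half_height = half_height,
         turns = as.integer(turns), label = label),
    class = "coil_spec"
  )
}

#' Ten-coil EMA system configuration
#'
#' The actuation system: an ordered list of exactly ten coils, the region of
#' interest (ROI) box in which control and localization are specified, and
#' per-coil current limits.
#'
#' @param coils List of ten [coil_spec()] objects.
#' @param roi Named list with `xlim`, `ylim`, `zlim` (metres).
#' @param current_limit Symmetric per-coil current limit, amperes.
#' @return An `ema_config` object.
#' @seealso [default_ema_config()]
#' @export
ema_config <- function(coils, roi, current_limit = 20) {
  if (length(coils) != 10L) abort("an EMA config requires exactly 10 coils")
  if (!all(vapply(coils, inherits, logical(1), "coil_spec"))) {
    abort("`coils` must all be coil_spec objects")
  }
  for (nm in c("xlim", "ylim", "zlim")) {
    if (is.null(roi[[nm]]) || diff(roi[[nm]]) <= 0) {
      abort(sprintf("roi$%s must be an increasing length-2 range", nm))
    }
  }
  structure(list(coils = coils, roi = roi, current_limit = current_limit),
            class = "ema_config")
}

#' Default ten-coil layout
#'
#' A declarative stand-in for the physical system: a Helmholtz pair along z
#' (uniform Bz), Maxwell (anti-Helmholtz) pairs along x and y (controllable
#' gradients), and rectangular pairs along x and y (uniform Bx, By), all
#' centred on the ROI. The ROI is a 100 mm x 100 mm x 40 mm box starting 5 mm
#' above the sensor plane (z = 0).
#'
#' @param current_limit Per-coil current limit, amperes.
#' @return An [ema_config()].
#' @examples
#' cfg <- default_ema_config()
#' length(cfg$coils)
#' @export
default_ema_config <- function(current_limit = 20) {
  zc <- 0.025 # ROI centre height, m
  r <- 0.25 # Helmholtz radius
  rm <- 0.20 # Maxwell radius; sized so 50 mT/m stays inside the current limit
  hh_sep <- r # Helmholtz condition
  mx_sep <- sqrt(3) * rm # Maxwell condition
  coils <- list(
    coil_spec("circular", c(0, 0, zc + hh_sep / 2), c(0, 0, 1), radius = r,
              turns = 200L, label = "helmholtz_z_up"),
    coil_spec("circular", c(0, 0, zc - hh_sep / 2), c(0, 0, 1), radius = r,
              turns = 200L, label = "helmholtz_z_down"),
    coil_spec("circular", c(+mx_sep / 2, 0, zc), c(1, 0, 0), radius = rm,
              turns = 400L, label = "maxwell_x_pos"),
    coil_spec("circular", c(-mx_sep / 2, 0, zc), c(-1, 0, 0), radius = rm,
              turns = 400L, label = "maxwell_x_neg"),
    coil_spec("circular", c(0, +mx_sep / 2, zc), c(0, 1, 0), radius = rm,
              turns = 400L, label = "maxwell_y_pos"),
    coil_spec("circular", c(0, -mx_sep / 2, zc), c(0, -1, 0), radius = rm,
              turns = 400L, label = "maxwell_y_neg"),
    # 0.20 m x 0.30 m rectangles standing tall along z: the tall aspect
    # keeps the in-plane field uniform and the allocation well conditioned
    # across the ROI
    coil_spec("rectangular", c(+0.13, 0, zc), c(1, 0, 0), half_width = 0.10,
              half_height = 0.15, turns = 150L, label = "rect_x_pos"),
    coil_spec("rectangular", c(-0.13, 0, zc), c(1, 0, 0), half_width = 0.10,
              half_height = 0.15, turns = 150L, label = "rect_x_neg"),
    coil_spec("rectangular", c(0, +0.13, zc), c(0, 1, 0), half_width = 0.10,
              half_height = 0.15, turns = 150L, label = "rect_y_pos"),
    coil_spec("rectangular", c(0, -0.13, zc), c(0, 1, 0), half_width = 0.10,
              half_height = 0.15, turns = 150L, label = "rect_y_neg")
  )
  ema_config(coils,
             roi = list(xlim = c(-0.05, 0.05), ylim = c(-0.05, 0.05),
                        zlim = c(0.005, 0.045)),
             current_limit = current_limit)
}

#' @export
print.ema_config <- function(x, ...) {
  cat("<ema_config> 10 coils\n")
  for (co in x$coils) {
    dims <- if (co$shape == "circular") sprintf("r = %.0f mm", 1e3 * co$radius)
            else sprintf("%.0f x %.0f mm", 2e3 * co$half_width, 2e3 * co$half_height)
    cat(sprintf("  %-16s %-11s %s, %d turns\n", co$label, co$shape, dims, co$turns))
  }
  cat(sprintf("  ROI x %s y %s z %s mm, limit +/-%g A\n",
              paste(1e3 * x$roi$xlim, collapse = ".."),
              paste(1e3 * x$roi$ylim, collapse = ".."),
              paste(1e3 * x$roi$zlim, collapse = ".."), x$current_limit))
  invisible(x)
}

in_roi <- function(roi, p) {
  p[1] >= roi$xlim[1] && p[1] <= roi$xlim[2] &&
    p[2] >= roi$ylim[1] && p[2] <= roi$ylim[2] &&
    p[3] >= roi$zlim[1] && p[3] <= roi$zlim[2]
}

#' Field of a circular filament loop
#'
#' Biot-Savart field per ampere of a circular loop of `turns` turns, via the
#' complete-elliptic-integral closed form (exact for a filament). On the axis
#' it reduces to `mu0 N R^2 / (2 (R^2 + z^2)^(3/2))`.
#'
#' @param coil A circular [coil_spec()].
#' @param point Evaluation point, 3-vector metres; must clear the filament by
#'   at least 0.5 mm.
#' @return Field 3-vector, Tesla per ampere.
#' @export
loop_field_circular <- function(coil, point) {
  point <- check_vec3(point)
  R <- frame_from_axis(coil$axis)
  q <- as.numeric(crossprod(R, point - coil$center)) # coil frame
  rho <- sqrt(q[1]^2 + q[2]^2)
  z <- q[3]
  a <- coil$radius
  alpha2 <- (a - rho)^2 + z^2
  if (sqrt(alpha2) < 5e-4) {
    abort(sprintf("point (%s) is within 0.5 mm of the coil filament '%s'",
                  paste(signif(point, 4), collapse = ", "), coil$label))
  }
  if (rho < 1e-9) {
    Bz <- MU0 * a^2 / (2 * (a^2 + z^2)^1.5)
    return(coil$turns * as.numeric(R %*% c(0, 0, Bz)))
  }
  beta2 <- (a + rho)^2 + z^2
  beta <- sqrt(beta2)
  m <- 4 * a * rho / beta2
  ke <- pracma::ellipke(m)
  K <- ke$k; E <- ke$e
  Bz <- MU0 / (2 * pi * beta) * (E * (a^2 - rho^2 - z^2) / alpha2 + K)
  Brho <- MU0 * z / (2 * pi * rho * beta) * (E * (a^2 + rho^2 + z^2) / alpha2 - K)
  b_local <- c(Brho * q[1] / rho, Brho * q[2] / rho, Bz)
  coil$turns * as.numeric(R %*% b_local)
}

## field of a finite straight filament segment carrying unit current,
## endpoints p1 -> p2, evaluated at x (all world frame); T/A
segment_field <- function(p1, p2, x) {
  a <- p1 - x
  b <- p2 - x
  na <- vnorm(a); nb <- vnorm(b)
  denom <- na * nb * (na * nb + sum(a * b))
  if (denom < 1e-18) {
    abort("field point lies on (or within numerical clearance of) a coil segment")
  }
  MU0 / (4 * pi) * (na + nb) / denom * cross3(a, b)
}

## perpendicular distance from x to segment p1-p2
segment_distance <- function(p1, p2, x) {
  d <- p2 - p1
  t <- sum((x - p1) * d) / sum(d * d)
  t <- max(0, min(1, t))
  vnorm(x - (p1 + t * d))
}

#' Field of a rectangular filament loop
#'
#' Exact four-segment analytic field per ampere of a rectangular loop of
#' `turns` turns. The loop lies in the plane through `center` normal to
#' `axis`, traversed counterclockwise about `axis`.
#'
#' @inheritParams loop_field_circular
#' @param coil A rectangular [coil_spec()].
#' @return Field 3-vector, Tesla per ampere.
#' @export
loop_field_rectangular <- function(coil, point) {
  point <- check_vec3(point)
  R <- frame_from_axis(coil$axis)
  w <- coil$half_width; h <- coil$half_height
  corners_local <- rbind(c(w, -h, 0), c(w, h, 0), c(-w, h, 0), c(-w, -h, 0))
  corners <- t(R %*% t(corners_local)) + matrix(coil$center, 4, 3, byrow = TRUE)
  B <- c(0, 0, 0)
  for (i in 1:4) {
    p1 <- corners[i, ]
    p2 <- corners[if (i == 4) 1 else i + 1, ]
    if (segment_distance(p1, p2, point) < 5e-4) {
      abort(sprintf("point (%s) is within 0.5 mm of the coil filament '%s'",
                    paste(signif(point, 4), collapse = ", "), coil$label))
    }
    B <- B + segment_field(p1, p2, point)
  }
  coil$turns * B
}

#' Unit-current field of any coil
#'
#' Dispatches on the coil shape.
#'
#' @inheritParams loop_field_circular
#' @return Field 3-vector, Tesla per ampere.
#' @export
coil_field <- function(coil, point) {
  if (coil$shape == "circular") loop_field_circular(coil, point)
  else loop_field_rectangular(coil, point)
}

#' Unit-current coil field basis at a set of points
#'
#' Evaluates every coil's unit-current field at every query point -- the
#' simulated analogue of the measured per-coil field database used for
#' external-field compensation. Deterministic in the configuration.
#'
#' @param config An [ema_config()].
#' @param points n x 3 matrix (or single 3-vector) of evaluation points, m.
#' @return A tibble with columns `coil` (index), `label`, `point` (index),
#'   `x`, `y`, `z` (m) and `bx`, `by`, `bz` (T/A).
#' @export
coil_basis <- function(config, points) {
  if (!is.matrix(points)) points <- matrix(check_vec3(points), 1L)
  if (nrow(points) == 0L) abort("`points` must be nonempty")
  rows <- purrr::map(seq_along(config$coils), function(k) {
    co <- config$coils[[k]]
    B <- t(apply(points, 1, function(p) coil_field(co, p)))
    tibble::tibble(coil = k, label = co$label, point = seq_len(nrow(points)),
                   x = points[, 1], y = points[, 2], z = points[, 3],
                   bx = B[, 1], by = B[, 2], bz = B[, 3])
  })
  dplyr::bind_rows(rows)
}

## n_sensors x 10 matrix of unit-current fields along the sensor axis (+z)
sensor_basis_matrix <- function(config, array) {
  S <- array$positions
  vapply(config$coils,
         function(co) apply(S, 1, function(p) coil_field(co, p)[3]),
         numeric(nrow(S)))
}

check_currents <- function(config, currents) {
  if (length(currents) != 10L || !all(is.finite(currents))) {
    abort("`currents` must be a finite numeric 10-vector (one entry per coil)")
  }
  if (any(abs(currents) > config$current_limit)) {
    warn(sprintf("current limit %g A exceeded (max |i| = %.3g A)",
                 config$current_limit, max(abs(currents))))
  }
  as.numeric(currents)
}

#' Superposed EMA field
#'
#' Field of the whole coil system at a point: the unit-current basis fields
#' weighted by the applied currents, `B = sum_k H_k(point) i_k`. Currents
#' beyond the configured limit raise a warning, not an error.
#'
#' @param config An [ema_config()].
#' @param currents Numeric 10-vector, amperes.
#' @param point Evaluation point, 3-vector metres.
#' @return Field 3-vector, Tesla.
#' @export
ema_field <- function(config, currents, point) {
  currents <- check_currents(config, currents)
  point <- check_vec3(point)
  B <- c(0, 0, 0)
  for (k in seq_along(config$coils)) {
    if (currents[k] != 0) B <- B + currents[k] * coil_field(config$coils[[k]], point)
  }
  B
}

#' EMA field gradient tensor
#'
#' Central-finite-difference gradient of [ema_field()] (fourth-order
#' five-point stencil, step `h`). In free space the tensor is symmetric and
#' traceless (curl- and divergence-free field); both hold here to the
#' truncation error of the stencil.
#'
#' @inheritParams ema_field
#' @param h Finite-difference step, metres.
#' @return 3x3 matrix, `[i, j] = dB_i / dx_j`, T/m.
#' @export
field_gradient_tensor <- function(config, currents, point, h = 1e-4) {
  point <- check_vec3(point)
  central_gradient(function(p) ema_field(config, currents, p), point, h)
}

## per-coil unit-current gradient tensor at a point
coil_gradient_tensor <- function(coil, point, h = 1e-4) {
  central_gradient(function(p) coil_field(coil, p), point, h)
}

## fourth-order central-difference Jacobian of a 3-vector field
central_gradient <- function(f, point, h) {
  G <- matrix(0, 3, 3)
  for (j in 1:3) {
    e <- c(0, 0, 0); e[j] <- h
    G[, j] <- (-f(point + 2 * e) + 8 * f(point + e) -
                 8 * f(point - e) + f(point - 2 * e)) / (12 * h)
  }
  G
}

#' Precomputed field grid with trilinear interpolation
#'
#' Tabulates each coil's unit-current field on a regular grid over the ROI
#' (mimicking a measured field database) and evaluates by trilinear
#' interpolation. Agreement with the analytic basis is better than 0.5 %
#' inside the ROI at the default resolution.
#'
#' @param config An [ema_config()].
#' @param n Grid points per axis.
#' @return A `field_grid` object usable with [ema_field_gridded()].
#' @export
build_field_grid <- function(config, n = 11L) {
  roi <- config$roi
  xs <- seq(roi$xlim[1], roi$xlim[2], length.out = n)
  ys <- seq(roi$ylim[1], roi$ylim[2], length.out = n)
  zs <- seq(roi$zlim[1], roi$zlim[2], length.out = n)
  tab <- array(NA_real_, c(n, n, n, 3, 10))
  for (k in 1:10) {
    co <- config$coils[[k]]
    for (i in seq_len(n)) for (j in seq_len(n)) for (l in seq_len(n)) {
      tab[i, j, l, , k] <- coil_field(co, c(xs[i], ys[j], zs[l]))
    }
  }
  structure(list(xs = xs, ys = ys, zs = zs, table = tab), class = "field_grid")
}

#' @rdname build_field_grid
#' @param grid A `field_grid` from [build_field_grid()].
#' @param currents Numeric 10-vector, amperes.
#' @param point Evaluation point inside the gridded box, 3-vector metres.
#' @return Field 3-vector, Tesla.
#' @export
ema_field_gridded <- function(grid, currents, point) {
  point <- check_vec3(point)
  locate <- function(ax, v) {
    if (v < ax[1] - 1e-12 || v > ax[length(ax)] + 1e-12) {
      abort("point outside the tabulated grid")
    }
    i <- max(1L, min(length(ax) - 1L, findInterval(v, ax)))
    list(i = i, t = (v - ax[i]) / (ax[i + 1] - ax[i]))
  }
  lx <- locate(grid$xs, point[1])
  ly <- locate(grid$ys, point[2])
  lz <- locate(grid$zs, point[3])
  B <- c(0, 0, 0)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) lx$t else 1 - lx$t) * (if (dy) ly$t else 1 - ly$t) *
      (if (dz) lz$t else 1 - lz$t)
    if (wgt == 0) next
    slab <- grid$table[lx$i + dx, ly$i + dy, lz$i + dz, , ] # 3 x 10
    B <- B + wgt * as.numeric(slab %*% currents)
  }
  B
}
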