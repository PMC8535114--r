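# Independent oracles used across the suite. Each one is written directly
# from first principles (Biot-Savart quadrature, elementary-dipole grids,
# energy gradients) and never calls the implementation path it checks.

MU0_T <- 4e-7 * pi

# Biot-Savart field of a polyline current path by fine segment quadrature
# (midpoint rule per segment), unit current.
oracle_biot_savart <- function(vertices, point) {
  B <- c(0, 0, 0)
  for (i in seq_len(nrow(vertices) - 1L)) {
    a <- vertices[i, ]
    b <- vertices[i + 1L, ]
    mid <- (a + b) / 2
    dl <- b - a
    r <- point - mid
    rn <- sqrt(sum(r * r))
    cr <- c(dl[2] * r[3] - dl[3] * r[2],
            dl[3] * r[1] - dl[1] * r[3],
            dl[1] * r[2] - dl[2] * r[1])
    B <- B + MU0_T / (4 * pi) * cr / rn^3
  }
  B
}

oracle_circle_vertices <- function(radius, n = 1e4) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  cbind(radius * cos(th), radius * sin(th), 0)
}

# field of a circular loop at `point`, loop in z = 0 plane centred on origin
oracle_loop_field <- function(radius, point, n = 1e4) {
  oracle_biot_savart(oracle_circle_vertices(radius, n), point)
}

# field of a rectangle (half sides w, h) in z = 0, counterclockwise, by
# subdividing each side into many segments
oracle_rect_field <- function(w, h, point, n_per_side = 2500) {
  corners <- rbind(c(w, -h, 0), c(w, h, 0), c(-w, h, 0), c(-w, -h, 0),
                   c(w, -h, 0))
  B <- c(0, 0, 0)
  for (i in 1:4) {
    t <- seq(0, 1, length.out = n_per_side + 1)
    seg <- outer(1 - t, corners[i, ]) + outer(t, corners[i + 1, ])
    B <- B + oracle_biot_savart(seg, point)
  }
  B
}

# cylinder magnet modelled as a dense grid of elementary dipoles (uniform
# magnetization along `heading`); total moment matches the magnet spec
oracle_magnet_grid_field <- function(spec, position, heading, point,
                                     diameter = 0.010, length = 0.012,
                                     n = 9) {
  # build the grid along the local axis frame
  w <- heading / sqrt(sum(heading^2))
  seed <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed - sum(seed * w) * w; u <- u / sqrt(sum(u * u))
  v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  s <- seq(-0.5, 0.5, length.out = n + 1)
  s <- (s[-1] + s[-length(s)]) / 2 # cell centres
  pts <- expand.grid(a = s * diameter, b = s * diameter, c = s * length)
  inside <- with(pts, a^2 + b^2 <= (diameter / 2)^2)
  pts <- pts[inside, ]
  m_each <- spec$moment / nrow(pts)
  B <- c(0, 0, 0)
  for (i in seq_len(nrow(pts))) {
    centre <- position + pts$a[i] * u + pts$b[i] * v + pts$c[i] * w
    r <- point - centre
    rn <- sqrt(sum(r * r))
    B <- B + MU0_T / (4 * pi) *
      (3 * sum(w * r) * r / rn^5 - w / rn^3) * m_each
  }
  B
}

# textbook dipole field written symbol-by-symbol from B(r) =
# mu0/(4 pi) * (3 (m.r_hat) r_hat - m) / |r|^3, independent of the package
oracle_dipole_field <- function(moment_vec, source, point) {
  r <- point - source
  rn <- sqrt(sum(r * r))
  rh <- r / rn
  MU0_T / (4 * pi) * (3 * sum(moment_vec * rh) * rh - moment_vec) / rn^3
}

# magnetic potential energy U = -m.B of a dipole in the coil field;
# the force oracle is -grad U by central differences
oracle_force_energy <- function(config, currents, spec, heading, point,
                                h = 1e-5) {
  U <- function(p) {
    -sum(spec$moment * heading * ema_field(config, currents, p))
  }
  -c(U(point + c(h, 0, 0)) - U(point - c(h, 0, 0)),
     U(point + c(0, h, 0)) - U(point - c(0, h, 0)),
     U(point + c(0, 0, h)) - U(point - c(0, 0, h))) / (2 * h)
}

# shared fixtures (cheap to build; constructed once per test file load)
test_spec <- function() magnet_spec()
test_array <- function() sensor_array()
test_config <- function() default_ema_config()
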