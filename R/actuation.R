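#' Actuation matrix
#'
#' Linear map from the ten coil currents to the six controlled quantities at a
#' workspace point P: rows 1-3 are the per-coil unit-current field components,
#' rows 4-6 the heading-projected gradient components
#' `(M_hat . grad) B_j` per unit current. Depends only on geometry and the
#' heading, never on current magnitudes.
#'
#' @param config An [ema_config()].
#' @param P Evaluation point inside the ROI, 3-vector metres.
#' @param heading Unit 3-vector, the capsule heading used for the gradient
#'   projection.
#' @return An `actuation_matrix` object: list with `matrix` (6 x 10),
#'   `eval_point`, `heading_used`.
#' @export
build_actuation_matrix <- function(config, P, heading) {
  P <- check_vec3(P)
  heading <- unitize(check_vec3(heading))
  if (!in_roi(config$roi, P)) {
    abort(sprintf("actuation point (%s) m is outside the ROI",
                  paste(signif(P, 4), collapse = ", ")))
  }
  X <- matrix(0, 6, 10)
  for (k in 1:10) {
    co <- config$coils[[k]]
    X[1:3, k] <- coil_field(co, P)
    G <- coil_gradient_tensor(co, P)
    # (M_hat . grad) B_j = sum_i heading_i dB_j/dx_i
    X[4:6, k] <- as.numeric(G %*% heading)
  }
  structure(list(matrix = X, eval_point = P, heading_used = heading),
            class = "actuation_matrix")
}

#' Desired field/gradient wrench
#'
#' The six-vector target of the current allocation: the field at the capsule
#' and the heading-projected gradient triple.
#'
#' @param field Desired field, 3-vector Tesla.
#' @param gradient Desired `(M_hat . grad) B` triple, 3-vector T/m.
#' @return A `desired_wrench` object.
#' @export
desired_wrench <- function(field, gradient) {
  structure(list(field = check_vec3(field), gradient = check_vec3(gradient)),
            class = "desired_wrench")
}

#' Minimum-norm current allocation
#'
#' Solves the underdetermined 6 x 10 system `X i = [B; (M_hat.grad)B]_desired`
#' by the Moore-Penrose pseudoinverse (SVD, relative singular-value cutoff
#' 1e-10), yielding the minimum-norm current vector. Rank deficiency is
#' reported in the attached diagnostics rather than raised.
#'
#' @param X An [build_actuation_matrix()] result (or bare 6 x 10 matrix).
#' @param desired A [desired_wrench()].
#' @param sv_cutoff Relative singular-value cutoff of the pseudoinverse.
#'   The default keeps every numerically nonzero direction (exact
#'   Moore-Penrose behaviour); controllers pass a larger cutoff (e.g. 1e-3)
#'   so that near-degenerate directions -- which buy microscopic wrench
#'   components at the price of tens of amperes -- are truncated instead of
#'   exploited.
#' @export
allocate_currents <- function(X, desired, sv_cutoff = 1e-10) {
  M <- if (inherits(X, "actuation_matrix")) X$matrix else X
  if (!is.matrix(M) || !all(dim(M) == c(6L, 10L)) || !all(is.finite(M))) {
    abort("actuation matrix must be a finite 6 x 10 matrix")
  }
  d <- c(desired$field, desired$gradient)
  if (!all(is.finite(d))) abort("desired wrench must be finite")
  sv <- svd(M)
  tol <- sv_cutoff * sv$d[1]
  keep <- sv$d > tol
  dinv <- ifelse(keep, 1 / sv$d, 0)
  i <- as.numeric(sv$v %*% (dinv * crossprod(sv$u, d)))
  attr(i, "residual") <- vnorm(as.numeric(M %*% i) - d)
  attr(i, "rank") <- sum(keep)
  attr(i, "condition") <- sv$d[1] / sv$d[min(6, sum(keep))]
  i
}

#' Map an operator command to the desired wrench
#'
#' The three-parameter user interface: yaw and pitch give the heading unit
#' vector `u = (cos p cos y, cos p sin y, sin p)`; the push magnitude `F`
#' (T/m) gives the gradient `F u`, and the field is `gamma F u`, keeping a
#' fixed field-to-gradient magnitude ratio `gamma` (default 0.1 m, i.e. the
#' 1:10 ratio of field in Tesla to gradient in Tesla per metre).
#'
#' @param yaw,pitch Command angles, radians.
#' @param F Push magnitude, T/m; must be nonnegative (reverse by flipping the
#'   heading, as the joystick's backward trigger does).
#' @param gamma Field:gradient ratio, metres.
#' @return A [desired_wrench()]; both components are parallel to the
#'   commanded heading.
#' @examples
#' w <- command_to_desired(0, 0, F = 0.05)
#' sqrt(sum(w$field^2)) # 5e-3 T for the default gamma
#' @export
command_to_desired <- function(yaw, pitch, F, gamma = 0.1) {
  if (F < 0) abort("`F` must be nonnegative; reverse by flipping yaw/pitch")
  if (gamma <= 0) abort("`gamma` must be positive")
  u <- heading_from_angles(yaw, pitch)
  grad <- F * u
  # field is gamma times the same vector, so the magnitude ratio is exact
  desired_wrench(field = gamma * grad, gradient = grad)
}
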