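#' Construct a quaternion
#'
#' Quaternions are stored as plain numeric vectors in scalar-first order
#' `(w, x, y, z)`. Unit quaternions represent 3D rotations; `q` and `-q`
#' encode the same rotation (double cover).
#'
#' @param w Scalar part.
#' @param x,y,z Vector part.
#' @return Numeric vector of length 4, `c(w, x, y, z)`.
#' @export
#' @examples
#' quat(1, 0, 0, 0)            # identity rotation
#' quat_normalize(quat(1, 0, 0, 1))
quat <- function(w, x = 0, y = 0, z = 0) {
  if (length(w) == 4L && missing(x)) return(as.numeric(w))
  c(w, x, y, z)
}

#' @rdname quat
#' @param q Quaternion (numeric length 4).
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-300) stop("cannot normalize a zero quaternion", call. = FALSE)
  q / n
}

#' Hamilton product of two quaternions
#'
#' @param a,b Quaternions in `(w, x, y, z)` order.
#' @return The product `a %*% b` as a quaternion; unit times unit is unit
#'   up to floating-point rounding.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion inverse
#'
#' Conjugate divided by squared norm; for a unit quaternion this is the
#' conjugate.
#'
#' @param q Nonzero quaternion.
#' @return The inverse quaternion, so that `quat_multiply(q, quat_inverse(q))`
#'   is the identity.
#' @export
quat_inverse <- function(q) {
  n2 <- sum(q^2)
  if (n2 < 1e-300) stop("cannot invert a zero quaternion", call. = FALSE)
  c(q[1], -q[2], -q[3], -q[4]) / n2
}

#' Normalized linear interpolation (Nlerp) between quaternions
#'
#' Interpolates linearly between `q0` and `q1` and renormalizes. The sign of
#' `q1` is flipped first when `dot(q0, q1) < 0` so the interpolation takes
#' the shorter of the two arcs (double-cover convention).
#'
#' @param q0,q1 Nonzero quaternions.
#' @param t Interpolation fraction in `[0, 1]`.
#' @return Unit quaternion.
#' @export
nlerp <- function(q0, q1, t) {
  stopifnot(t >= 0, t <= 1)
  if (sum(q0 * q1) < 0) q1 <- -q1
  m <- (1 - t) * q0 + t * q1
  n <- sqrt(sum(m^2))
  if (n < 1e-12) stop("nlerp interpolants cancel to the zero vector", call. = FALSE)
  m / n
}

#' Angular difference between two rotations
#'
#' The rotation angle (radians) taking `q_true` to `q_est`, computed as
#' `2*acos(|w|)` of the relative quaternion `q_est * q_true^-1`. The absolute
#' value of the scalar part is taken before `acos` so that `q` and `-q`
#' (the same physical rotation) give an angle of zero; the result lies in
#' `[0, pi]`.
#'
#' @param q_est,q_true Unit quaternions.
#' @param tol Unit-norm tolerance for input validation.
#' @return Angle in radians, in `[0, pi]`.
#' @export
angular_difference <- function(q_est, q_true, tol = 1e-6) {
  if (abs(sum(q_est^2) - 1) > tol || abs(sum(q_true^2) - 1) > tol) {
    stop("angular_difference requires unit quaternions", call. = FALSE)
  }
  rel <- quat_multiply(q_est, quat_inverse(q_true))
  2 * acos(min(1, max(-1, abs(rel[1]))))
}

#' Construct a rigid-body pose with velocities
#'
#' A pose is the 14-component tracking state: position (3), unit orientation
#' quaternion (4), translational velocity (3) and a rotational-velocity
#' quaternion increment (4). The orientation is renormalized on construction;
#' the rotational velocity is a velocity, not an orientation, and is never
#' normalized.
#'
#' @param p Position, numeric length 3 (meters).
#' @param q Orientation quaternion (normalized on construction).
#' @param v_trans Translational velocity, numeric length 3 (meters per time
#'   step).
#' @param v_rot Rotational-velocity quaternion increment, numeric length 4
#'   (dimensionless per time step); the zero quaternion means "not rotating".
#' @return Object of class `"pose"`.
#' @export
#' @examples
#' pose(p = c(0, 0, 0.6))
pose <- function(p = c(0, 0, 0), q = quat(1, 0, 0, 0),
                 v_trans = c(0, 0, 0), v_rot = c(0, 0, 0, 0)) {
  stopifnot(length(p) == 3L, length(q) == 4L,
            length(v_trans) == 3L, length(v_rot) == 4L)
  structure(list(p = as.numeric(p), q = quat_normalize(q),
                 v_trans = as.numeric(v_trans), v_rot = as.numeric(v_rot)),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat("pose: p = (", paste(signif(x$p, 4), collapse = ", "),
      "), q = (", paste(signif(x$q, 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Integrate a pose one time step forward
#'
#' Backward-Euler style update: the new position is `p + v_trans * dt`; the
#' new orientation is the renormalized sum `q + 0.5 * (q x v_rot) * dt`
#' (equivalently an Nlerp between the old orientation and the velocity-rotated
#' one). Velocities are left untouched.
#'
#' @param pose A [pose()].
#' @param dt Time step (> 0), in the same time unit as the velocities.
#' @return List with elements `p` (new position) and `q` (new unit
#'   orientation).
#' @export
integrate_pose <- function(pose, dt) {
  stopifnot(inherits(pose, "pose"), dt > 0)
  p_new <- pose$p + pose$v_trans * dt
  qdot <- 0.5 * quat_multiply(pose$q, pose$v_rot)
  q_raw <- pose$q + qdot * dt
  n <- sqrt(sum(q_raw^2))
  # a pathological v_rot could cancel q entirely; keep the old orientation then
  q_new <- if (n < 1e-12) pose$q else q_raw / n
  list(p = p_new, q = q_new)
}
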