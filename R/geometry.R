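# Rotation and small-geometry helpers shared across modules.
#
# Orientations are proper rotations stored as 3x3 matrices; generalized
# rotation coordinates are axis-angle (rotation-vector) increments composed
# onto a reference rotation, so no global chart singularity is ever reached.

#' Skew-symmetric (cross-product) matrix of a 3-vector
#' @param v numeric length-3 vector.
#' @return 3x3 matrix `K` with `K %*% x == v x x` (cross product).
#' @keywords internal
skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

#' Rotation matrix from a rotation vector (SO(3) exponential map)
#'
#' @param theta rotation vector (radians); its norm is the rotation angle,
#'   its direction the rotation axis.
#' @return 3x3 proper rotation matrix.
#' @export
rot_exp <- function(theta) {
  phi <- sqrt(sum(theta^2))
  K <- skew3(theta)
  if (phi < 1e-8) {
    # second-order Taylor expansion; exact to machine precision at this size
    diag(3) + K + 0.5 * (K %*% K)
  } else {
    diag(3) + (sin(phi) / phi) * K + ((1 - cos(phi)) / phi^2) * (K %*% K)
  }
}

#' Right Jacobian of the SO(3) exponential map
#'
#' Relates perturbations of the rotation vector to body-frame angular
#' perturbations: d(exp(theta)) = exp(theta) * skew(Jr(theta) dtheta).
#' Used to form analytic gradients of energies that depend on rotated points.
#'
#' @param theta rotation vector (radians).
#' @return 3x3 matrix.
#' @keywords internal
rot_right_jacobian <- function(theta) {
  phi <- sqrt(sum(theta^2))
  K <- skew3(theta)
  if (phi < 1e-6) {
    diag(3) - 0.5 * K + (K %*% K) / 6
  } else {
    diag(3) - ((1 - cos(phi)) / phi^2) * K + ((phi - sin(phi)) / phi^3) * (K %*% K)
  }
}

#' Unit quaternion (w, x, y, z) from a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return numeric length-4, unit norm, w first.
#' @keywords internal
rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

#' Rotation matrix from a unit quaternion (w, x, y, z)
#' @param q numeric length-4.
#' @return 3x3 rotation matrix.
#' @keywords internal
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Construct a pose
#'
#' A pose is a rigid placement: a position (mm) plus a proper rotation.
#'
#' @param position numeric length-3, mm.
#' @param rotation 3x3 proper rotation matrix (default identity).
#' @return object of class `pedmech_pose`.
#' @export
pose <- function(position = c(0, 0, 0), rotation = diag(3)) {
  stopifnot(length(position) == 3, all(dim(rotation) == c(3, 3)))
  if (abs(det(rotation) - 1) > 1e-9)
    stop("pose rotation must be proper (determinant +1)")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("pose rotation must be orthonormal")
  structure(list(position = as.numeric(position), rotation = rotation),
            class = "pedmech_pose")
}

#' Apply a pose to local points
#' @param p `pedmech_pose`.
#' @param pts n x 3 matrix of local coordinates (mm).
#' @return n x 3 matrix of world coordinates.
#' @keywords internal
pose_apply <- function(p, pts) {
  pts <- rbind(pts)
  sweep(pts %*% t(p$rotation), 2, p$position, "+")
}

# signed angle (degrees) from vector a to vector b about axis n (all 3-vectors);
# a and b are projected onto the plane normal to n first.
signed_angle_about <- function(a, b, n) {
  n <- n / sqrt(sum(n^2))
  pa <- a - sum(a * n) * n
  pb <- b - sum(b * n) * n
  la <- sqrt(sum(pa^2)); lb <- sqrt(sum(pb^2))
  if (la < 1e-12 || lb < 1e-12) stop("degenerate projection in angle computation")
  s <- sum(crossprod3(pa, pb) * n)
  c <- sum(pa * pb)
  atan2(s, c) * 180 / pi
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
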