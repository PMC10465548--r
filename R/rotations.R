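#' Rotation utilities
#'
#' Rigid-body orientations are represented as unit quaternions
#' `c(w, x, y, z)`; rotation matrices act on row-vector coordinates as
#' `X %*% t(R)`.
#'
#' @name rotations
#' @keywords internal
NULL

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q numeric length-4 quaternion `c(w, x, y, z)`; normalised
#'   internally.
#' @return 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  stopifnot(length(q) == 4, all(is.finite(q)))
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Uniform random unit quaternions
#'
#' Draws orientations uniformly over SO(3) by normalising 4-variate
#' standard normals.
#'
#' @param n number of quaternions.
#' @return n x 4 matrix, one unit quaternion per row.
#' @export
random_quaternions <- function(n) {
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  q / sqrt(rowSums(q^2))
}

#' Quaternion for a rotation about an axis
#' @param axis 3-vector (normalised internally).
#' @param angle rotation angle, radians.
#' @return unit quaternion.
#' @export
axis_angle_quat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Hamilton product of two quaternions
#' @param a,b quaternions `c(w,x,y,z)`.
#' @return quaternion of the composed rotation (a then applied after b).
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Angular distance between rotations
#'
#' Geodesic angle (radians) between the rotations represented by two unit
#' quaternions, `2*acos(|<q1,q2>|)`.
#'
#' @param q1 unit quaternion or n x 4 matrix.
#' @param q2 unit quaternion.
#' @return angle(s) in radians, in \[0, pi\].
#' @export
quat_angle <- function(q1, q2) {
  if (is.matrix(q1)) {
    d <- abs(as.vector(q1 %*% q2))
  } else {
    d <- abs(sum(q1 * q2))
  }
  2 * acos(pmin(1, d))
}

identity_quat <- function() c(1, 0, 0, 0)
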