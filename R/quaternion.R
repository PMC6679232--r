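# Quaternion helpers. Convention throughout the package: q = c(w, x, y, z),
# unit norm, rotating sensor-frame vectors into the NED frame
# (v_ned = R(q) v_sensor). Row-wise variants operate on n x 4 matrices.

#' Quaternion utilities
#'
#' Small set of unit-quaternion operations used by the orientation filter and
#' the synthetic-session generator. Quaternions are numeric vectors
#' `c(w, x, y, z)`; the matrix variants take one quaternion per row.
#'
#' @param q,a,b Quaternions as length-4 vectors (`quat_*`) or n x 4 matrices
#'   (`quat_*_rows`).
#' @param axis Unit 3-vector rotation axis.
#' @param angle Rotation angle in radians (vectorised in `quat_from_axis_angle`).
#' @name quaternion
NULL

#' @rdname quaternion
#' @export
quat_multiply <- function(a, b) {
  c(a[1]*b[1] - a[2]*b[2] - a[3]*b[3] - a[4]*b[4],
    a[1]*b[2] + a[2]*b[1] + a[3]*b[4] - a[4]*b[3],
    a[1]*b[3] - a[2]*b[4] + a[3]*b[1] + a[4]*b[2],
    a[1]*b[4] + a[2]*b[3] - a[3]*b[2] + a[4]*b[1])
}

#' @rdname quaternion
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' @rdname quaternion
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' @rdname quaternion
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  if (length(angle) == 1L) {
    c(cos(angle/2), sin(angle/2) * axis)
  } else {
    cbind(cos(angle/2), sin(angle/2) %o% axis)
  }
}

#' Rotate a vector by a quaternion (sensor frame to NED)
#'
#' @param q Unit quaternion `c(w, x, y, z)`.
#' @param v 3-vector in the sensor frame.
#' @return 3-vector in the NED frame. Use [quat_conjugate()] to rotate the
#'   other way.
#' @export
quat_rotate <- function(q, v) {
  p <- quat_multiply(quat_multiply(q, c(0, v)), quat_conjugate(q))
  p[2:4]
}

# Row-wise Hamilton product of two n x 4 matrices.
quat_multiply_rows <- function(a, b) {
  cbind(a[,1]*b[,1] - a[,2]*b[,2] - a[,3]*b[,3] - a[,4]*b[,4],
        a[,1]*b[,2] + a[,2]*b[,1] + a[,3]*b[,4] - a[,4]*b[,3],
        a[,1]*b[,3] - a[,2]*b[,4] + a[,3]*b[,1] + a[,4]*b[,2],
        a[,1]*b[,4] + a[,2]*b[,3] - a[,3]*b[,2] + a[,4]*b[,1])
}

quat_conjugate_rows <- function(q) cbind(q[,1], -q[,2], -q[,3], -q[,4])

quat_normalize_rows <- function(q) q / sqrt(rowSums(q^2))

# Spherical linear interpolation between two fixed quaternions for a vector
# of weights in [0, 1].
quat_slerp_rows <- function(qa, qb, w) {
  d <- sum(qa * qb)
  if (d < 0) { qb <- -qb; d <- -d }
  if (d > 1 - 1e-10) {
    out <- (1 - w) %o% qa + w %o% qb
    return(quat_normalize_rows(out))
  }
  th <- acos(pmin(1, d))
  s <- sin(th)
  (sin((1 - w) * th) / s) %o% qa + (sin(w * th) / s) %o% qb
}
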