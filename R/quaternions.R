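# Vectorised unit-quaternion utilities. All quaternions are scalar-first
# rows (w, x, y, z) of an n x 4 matrix; rotations act as space-frame maps
# R(q) %*% v_body. Antipodal quaternions encode the same rotation, so the
# flow restricts to the q0 >= 0 hemisphere of S^3.

quat_normalize <- function(q) {
  q / sqrt(rowSums(q^2))
}

quat_conjugate <- function(q) {
  cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])
}

# Hamilton product a (x) b, rowwise
quat_multiply <- function(a, b) {
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  cbind(w, x, y, z)
}

# n x 9 rotation-matrix entries in column-major order (R11,R21,R31,R12,...)
quat_to_rotmat <- function(q) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  )
}

# Inverse of quat_to_rotmat, vectorised Shepperd extraction: pick, per row,
# the numerically largest of the four candidate components.
rotmat_to_quat <- function(R) {
  R11 <- R[, 1]; R21 <- R[, 2]; R31 <- R[, 3]
  R12 <- R[, 4]; R22 <- R[, 5]; R32 <- R[, 6]
  R13 <- R[, 7]; R23 <- R[, 8]; R33 <- R[, 9]
  tr <- R11 + R22 + R33
  m <- cbind(1 + tr, 1 + R11 - R22 - R33, 1 - R11 + R22 - R33, 1 - R11 - R22 + R33)
  pick <- max.col(m, ties.method = "first")
  n <- nrow(R)
  q <- matrix(0, n, 4)
  i <- pick == 1L
  if (any(i)) {
    S <- 2 * sqrt(pmax(m[i, 1], 0))
    q[i, ] <- cbind(S / 4, (R32[i] - R23[i]) / S, (R13[i] - R31[i]) / S,
                    (R21[i] - R12[i]) / S)
  }
  i <- pick == 2L
  if (any(i)) {
    S <- 2 * sqrt(pmax(m[i, 2], 0))
    q[i, ] <- cbind((R32[i] - R23[i]) / S, S / 4, (R12[i] + R21[i]) / S,
                    (R13[i] + R31[i]) / S)
  }
  i <- pick == 3L
  if (any(i)) {
    S <- 2 * sqrt(pmax(m[i, 3], 0))
    q[i, ] <- cbind((R13[i] - R31[i]) / S, (R12[i] + R21[i]) / S, S / 4,
                    (R23[i] + R32[i]) / S)
  }
  i <- pick == 4L
  if (any(i)) {
    S <- 2 * sqrt(pmax(m[i, 4], 0))
    q[i, ] <- cbind((R21[i] - R12[i]) / S, (R13[i] + R31[i]) / S,
                    (R23[i] + R32[i]) / S, S / 4)
  }
  quat_normalize(q)
}

#' Fix a unit quaternion onto the q0 >= 0 hemisphere
#'
#' `q` and `-q` encode the same rotation; the flow therefore works on the
#' closed hemisphere of \eqn{S^3} with non-negative scalar part. The
#' measure-zero boundary case `q0 = 0` is resolved by the convention
#' `sign(0) = +1`, i.e. such quaternions are returned unchanged.
#'
#' @param q numeric matrix (n x 4) of unit quaternions, scalar first.
#' @return matrix of the same shape with non-negative first column and
#'   identical rotation matrices.
#' @export
#' @examples
#' fix_hemisphere(matrix(c(-1, 0, 0, 0), 1))
fix_hemisphere <- function(q) {
  q <- as.matrix(q)
  if (ncol(q) != 4) abort("expected an n x 4 quaternion matrix")
  s <- ifelse(q[, 1] < 0, -1, 1)
  q * s
}

#' Map hemisphere quaternions to hyperspherical angles (and back)
#'
#' Standard hyperspherical coordinates restricted to the `q0 >= 0` hemisphere:
#' \deqn{q = (\cos\theta_0,\ \sin\theta_0\cos\theta_1,\
#'            \sin\theta_0\sin\theta_1\cos\theta_2,\
#'            \sin\theta_0\sin\theta_1\sin\theta_2)}
#' with \eqn{\theta_0 \in [0, \pi/2]}, \eqn{\theta_1 \in [0, \pi]},
#' \eqn{\theta_2 \in [0, 2\pi)}. The log-volume change in the angles-to-
#' quaternion direction is \eqn{\ln(\sin^2\theta_0 \sin\theta_1)} (negated
#' for the opposite direction); the log argument is clipped below at `clip`
#' so samples near the coordinate singularities stay finite. At singular
#' points the undefined angles are set to 0, deterministically.
#'
#' @param q matrix (n x 4) of hemisphere-fixed unit quaternions.
#' @param clip lower clip for the log-volume argument.
#' @return list with `angles` (n x 3 matrix theta0, theta1, theta2) and
#'   `log_volume` (length-n, direction quaternion -> angles).
#' @export
#' @examples
#' quat_to_hyperspherical(matrix(c(1, 1, 1, 1) / 2, 1))
quat_to_hyperspherical <- function(q, clip = 1e-8) {
  q0 <- pmin(pmax(q[, 1], -1), 1)
  theta0 <- acos(q0)
  s0 <- sqrt(pmax(1 - q0^2, 0))
  sing0 <- s0 < 1e-14
  c1 <- ifelse(sing0, 1, pmin(pmax(q[, 2] / pmax(s0, 1e-300), -1), 1))
  theta1 <- acos(c1)
  s1 <- sqrt(pmax(1 - c1^2, 0))
  sing1 <- sing0 | (s1 < 1e-14)
  theta2 <- atan2(q[, 4], q[, 3])
  theta2 <- ifelse(theta2 < 0, theta2 + 2 * pi, theta2)
  theta1[sing0] <- 0
  theta2[sing1] <- 0
  lv <- -log(pmax(s0^2 * s1, clip))
  list(angles = cbind(theta0, theta1, theta2, deparse.level = 0),
       log_volume = lv, singular = sing0 | sing1)
}

#' @rdname quat_to_hyperspherical
#' @param angles matrix (n x 3) of hyperspherical angles.
#' @return for `hyperspherical_to_quat`: list with `q` (n x 4) and
#'   `log_volume` (direction angles -> quaternion).
#' @export
hyperspherical_to_quat <- function(angles, clip = 1e-8) {
  t0 <- angles[, 1]; t1 <- angles[, 2]; t2 <- angles[, 3]
  s0 <- sin(t0); s1 <- sin(t1)
  q <- cbind(cos(t0), s0 * cos(t1), s0 * s1 * cos(t2), s0 * s1 * sin(t2))
  lv <- log(pmax(s0^2 * s1, clip))
  list(q = quat_normalize(q), log_volume = lv)
}

# Uniform quaternions on the q0 >= 0 hemisphere of S^3
runif_hemisphere_quat <- function(n) {
  q <- matrix(rnorm(4 * n), n, 4)
  fix_hemisphere(quat_normalize(q))
}
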