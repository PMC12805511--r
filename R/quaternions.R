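# Quaternion and Euler-angle utilities (scalar-first quaternions, ZYZ
# Euler convention).

#' Rotation matrix from a unit quaternion
#'
#' Scalar-first quaternion (Q0, Q1, Q2, Q3).  The returned matrix maps
#' molecule-fixed (MF) coordinates to laboratory-frame coordinates; its
#' columns are the MF axes expressed in the LF.
#'
#' @param Q Numeric length-4 quaternion.
#' @return 3 x 3 rotation matrix.
#' @export
quat_to_rotmat <- function(Q) {
  w <- Q[1]; x <- Q[2]; y <- Q[3]; z <- Q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' ZYZ Euler angles
#'
#' `euler_to_rotmat` composes R = Rz(alpha) Ry(beta) Rz(gamma);
#' `rotmat_to_euler_zyz` inverts it with alpha, gamma in (-pi, pi] and
#' beta in [0, pi].  At the beta = 0 or pi singularity gamma is set to 0.
#'
#' @param alpha,beta,gamma Euler angles in radians.
#' @return For `euler_to_rotmat`, a 3 x 3 rotation matrix.
#' @export
euler_to_rotmat <- function(alpha, beta, gamma) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0,
                             sin(t), cos(t), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t),
                             0, 1, 0,
                             -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

#' @rdname euler_to_rotmat
#' @param R 3 x 3 rotation matrix.
#' @return For `rotmat_to_euler_zyz`, a named vector (alpha, beta, gamma).
#' @export
rotmat_to_euler_zyz <- function(R) {
  beta <- acos(max(-1, min(1, R[3, 3])))
  if (abs(R[3, 3]) > 1 - 1e-12) {
    gamma <- 0
    alpha <- atan2(R[2, 1], R[1, 1])
    if (R[3, 3] < 0) alpha <- -alpha
  } else {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  }
  c(alpha = alpha, beta = beta, gamma = gamma)
}

#' Rank-2 D2_00 series of a quaternion trajectory
#'
#' D2_00(Omega(t)) = (3 cos^2(beta) - 1)/2 with cos(beta) the (3,3)
#' element of the rotation matrix, computed vectorized.
#'
#' @param Qmat n x 4 matrix of quaternions.
#' @return Numeric vector of length n.
#' @export
quat_d200_series <- function(Qmat) {
  c33 <- 1 - 2 * (Qmat[, 2]^2 + Qmat[, 3]^2)
  (3 * c33^2 - 1) / 2
}

#' Euler-angle time series of a quaternion trajectory
#' @param Qmat n x 4 matrix of quaternions.
#' @return n x 3 matrix with columns alpha, beta, gamma.
#' @export
quat_series_to_euler <- function(Qmat) {
  out <- t(apply(Qmat, 1, function(q) rotmat_to_euler_zyz(quat_to_rotmat(q))))
  colnames(out) <- c("alpha", "beta", "gamma")
  out
}
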