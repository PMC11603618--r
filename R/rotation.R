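# Quaternion and rotation helpers. Quaternions are length-4 numeric
# vectors (w, x, y, z), unit norm. Orientation increments use the SO(3)
# exponential map (axis-angle 3-vectors, radians).

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, ncol = 3)
}

axis_angle_to_quat <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-300) return(c(1, 0, 0, 0))
  c(cos(th / 2), sin(th / 2) * v / th)
}

skew <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

# Rotation matrix of the exponential map exp([v]_x).
expmap <- function(v) {
  th <- sqrt(sum(v^2))
  K <- skew(v)
  if (th < 1e-8) return(diag(3) + K + 0.5 * K %*% K)
  diag(3) + sin(th) / th * K + (1 - cos(th)) / th^2 * K %*% K
}

# Left Jacobian of SO(3): d/ds exp([v + s w]_x) |_{s=0} = [J_l(v) w]_x exp([v]_x).
so3_left_jacobian <- function(v) {
  th <- sqrt(sum(v^2))
  K <- skew(v)
  if (th < 1e-6) return(diag(3) + 0.5 * K + K %*% K / 6)
  diag(3) + (1 - cos(th)) / th^2 * K + (th - sin(th)) / th^3 * K %*% K
}

mat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_normalize(q)
}

#' ZYZ Euler angles of a rotation
#'
#' Exports an orientation quaternion as ZYZ Euler angles (radians),
#' for interoperability with codes that parametrize molecular
#' orientations by Euler angles.
#'
#' @param q Unit quaternion (w, x, y, z).
#' @return Numeric length-3 vector (alpha, beta, gamma), with
#'   `R = Rz(alpha) %*% Ry(beta) %*% Rz(gamma)`.
#' @export
quat_to_euler_zyz <- function(q) {
  R <- quat_to_mat(quat_normalize(q))
  beta <- acos(max(-1, min(1, R[3, 3])))
  if (abs(sin(beta)) < 1e-12) {
    alpha <- atan2(R[2, 1], R[1, 1])
    return(c(alpha, beta, 0))
  }
  alpha <- atan2(R[2, 3], R[1, 3])
  gamma <- atan2(R[3, 2], -R[3, 1])
  c(alpha, beta, gamma)
}
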