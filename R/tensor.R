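#' Quadrupolar coupling tensor
#'
#' Describes a site's electric-field-gradient tensor by its quadrupolar
#' coupling constant `Cq = e^2 q Q / h` (Hz), asymmetry `eta` in `[0, 1]`
#' (principal values ordered `|q_zz| >= |q_yy| >= |q_xx|`), and the ZYZ Euler
#' angles (rad, active convention) rotating the principal-axis system into
#' the crystallite frame.
#'
#' @param cq_hz quadrupolar coupling constant, Hz (non-negative).
#' @param eta asymmetry parameter in `[0, 1]`.
#' @param euler numeric length-3, ZYZ Euler angles (rad) of the principal-axis
#'   system in the crystallite frame.
#' @return Object of class `quad_tensor`.
#' @examples
#' quad_tensor(55.3e3)
#' @export
quad_tensor <- function(cq_hz, eta = 0, euler = c(0, 0, 0)) {
  stopifnot(is.numeric(cq_hz), length(cq_hz) == 1, cq_hz >= 0,
            is.numeric(eta), length(eta) == 1, eta >= 0, eta <= 1,
            is.numeric(euler), length(euler) == 3)
  structure(list(cq_hz = cq_hz, eta = eta, euler = as.numeric(euler)),
            class = "quad_tensor")
}

#' @export
print.quad_tensor <- function(x, ...) {
  cat(sprintf("<quad_tensor> Cq = %.4g kHz, eta = %.3g, euler = (%.3f, %.3f, %.3f) rad\n",
              x$cq_hz / 1e3, x$eta, x$euler[1], x$euler[2], x$euler[3]))
  invisible(x)
}

#' Crystallite orientation
#'
#' Orientation of one crystallite with respect to the rotor (spinning) axis:
#' `beta` is the polar angle and `alpha` the azimuthal angle of the
#' crystallite frame's z-axis about the rotor axis, with a powder weight.
#'
#' @param alpha azimuthal angle, rad.
#' @param beta polar angle, rad, in `[0, pi]`.
#' @param weight powder weight (weights over a powder set sum to 1).
#' @return Object of class `crystallite`.
#' @export
crystallite <- function(alpha, beta, weight = 1) {
  stopifnot(beta >= 0, beta <= pi, weight >= 0)
  structure(list(alpha = alpha, beta = beta, weight = weight),
            class = "crystallite")
}

rot_z <- function(a) {
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
rot_y <- function(b) {
  matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
}
# active ZYZ rotation R = Rz(a) Ry(b) Rz(g)
euler_rot <- function(e) rot_z(e[1]) %*% rot_y(e[2]) %*% rot_z(e[3])

#' Magic angle
#'
#' `acos(1/sqrt(3))`, the rotor tilt (about 54.74 deg) at which the secular
#' part of rank-2 anisotropic interactions averages to zero under spinning.
#'
#' @return angle in radians.
#' @export
magic_angle <- function() acos(1 / sqrt(3))

# normalized traceless PAS tensor, q_zz = 1
pas_tensor <- function(eta) diag(c((eta - 1) / 2, -(eta + 1) / 2, 1))

# normalized tensor in the crystallite frame
tensor_in_crystallite <- function(tensor) {
  R <- euler_rot(tensor$euler)
  R %*% pas_tensor(tensor$eta) %*% t(R)
}

#' Static quadrupolar frequency
#'
#' Secular quadrupolar frequency (rad/s) of a deuteron whose tensor sits at
#' polar/azimuthal angles `(theta, phi)` to the static field:
#' `wQ = (3 pi / 2) Cq ((3 cos^2 theta - 1)/2 + (eta/2) sin^2 theta cos 2 phi)`.
#' The two single-quantum lines of the corresponding spectrum appear at
#' `+/- wQ / 2 pi` Hz.  For a tensor with non-zero Euler angles, `(theta, phi)`
#' give the field direction in the crystallite frame.
#'
#' @param tensor a [quad_tensor()].
#' @param theta,phi field direction polar/azimuthal angles, rad.
#' @return angular frequency, rad/s (vectorized over `theta`/`phi`).
#' @export
quad_frequency_static <- function(tensor, theta, phi = 0) {
  n <- max(length(theta), length(phi))
  theta <- rep_len(theta, n); phi <- rep_len(phi, n)
  A <- tensor_in_crystallite(tensor)
  st <- sin(theta)
  bx <- st * cos(phi); by <- st * sin(phi); bz <- cos(theta)
  quad_form <- A[1, 1] * bx^2 + A[2, 2] * by^2 + A[3, 3] * bz^2 +
    2 * (A[1, 2] * bx * by + A[1, 3] * bx * bz + A[2, 3] * by * bz)
  (3 * pi / 2) * tensor$cq_hz * quad_form
}

#' Time-dependent quadrupolar frequency under MAS
#'
#' Secular quadrupolar frequency (rad/s) at time `t` for a crystallite
#' spinning at the magic angle.  For an axially symmetric tensor (`eta = 0`,
#' zero Euler angles) this reduces to the closed form
#' `wQ(t) = (3 pi / 4) Cq (sqrt(2) sin 2 beta sin(w t + a) - sin^2 beta cos(2 w t + 2 a))`,
#' which averages to zero over every rotor period.  The general case
#' (`eta > 0` or a tilted tensor) is computed by rotating the full
#' second-rank Cartesian tensor through crystallite, rotor and magic-angle
#' frames and reading the secular lab-frame component.
#'
#' Conventions: the crystallite-to-rotor rotation is `Rz(-alpha) Ry(beta)`,
#' and the static-field direction seen in the rotor frame at time `t` is
#' `(sin(theta_m) sin(w t), -sin(theta_m) cos(w t), cos(theta_m))` with
#' `theta_m = acos(1/sqrt(3))`.
#'
#' @param tensor a [quad_tensor()].
#' @param orient a [crystallite()].
#' @param t time or vector of times, s.
#' @param omega_mas spinning angular frequency, rad/s.
#' @return angular frequency wQ(t), rad/s (vectorized over `t`).
#' @export
quad_frequency_mas <- function(tensor, orient, t, omega_mas) {
  Rc <- rot_z(-orient$alpha) %*% rot_y(orient$beta)
  A <- Rc %*% tensor_in_crystallite(tensor) %*% t(Rc)
  sm <- sqrt(2 / 3); cm <- 1 / sqrt(3)  # sin/cos of the magic angle
  wt <- omega_mas * t
  bx <- sm * sin(wt); by <- -sm * cos(wt); bz <- cm
  quad_form <- A[1, 1] * bx^2 + A[2, 2] * by^2 + A[3, 3] * bz^2 +
    2 * (A[1, 2] * bx * by + A[1, 3] * bx * bz + A[2, 3] * by * bz)
  (3 * pi / 2) * tensor$cq_hz * quad_form
}

#' Effective tensor after fast rotation about an axis
#'
#' Averages the Cartesian tensor over `n_sites` orientations equally spaced in
#' azimuth on a cone of half-angle `cone_angle` about the crystallite z-axis,
#' the fast-limit result for an n-site hop (e.g. methyl three-site jumps).
#' For an axially symmetric input and `n_sites >= 3` the result is axially
#' symmetric along the rotation axis with
#' `Cq_eff = Cq |3 cos^2(cone_angle) - 1| / 2`; the tetrahedral methyl
#' geometry (109.47 deg) gives `Cq_eff = Cq / 3`.
#'
#' @param tensor a [quad_tensor()] (orientation relative to the cone axis).
#' @param cone_angle angle between the tensor z-axis and the rotation axis, rad.
#' @param n_sites number of equally spaced sites, `>= 3`.
#' @return a [quad_tensor()] for the averaged interaction.
#' @export
average_tensor_fast_rotation <- function(tensor, cone_angle, n_sites = 3) {
  if (cone_angle < 0 || cone_angle > pi) {
    stop("`cone_angle` must lie in [0, pi]")
  }
  stopifnot(n_sites >= 3)
  q <- tensor_in_crystallite(tensor)
  A <- matrix(0, 3, 3)
  for (k in seq_len(n_sites)) {
    R <- rot_z(2 * pi * (k - 1) / n_sites) %*% rot_y(cone_angle)
    A <- A + R %*% q %*% t(R)
  }
  A <- A / n_sites
  tensor_from_cartesian(A, tensor$cq_hz)
}

# Convert a (normalized, traceless, symmetric) Cartesian tensor back into
# (Cq_eff, eta_eff, euler): eigenvalues ordered |zz| >= |yy| >= |xx|,
# axes chosen so eta >= 0.
tensor_from_cartesian <- function(A, cq_hz) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  ord <- order(abs(e$values))          # |xx| <= |yy| <= |zz|
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  zz <- vals[3]
  if (abs(zz) < 1e-14) {
    return(quad_tensor(0, 0, c(0, 0, 0)))
  }
  eta <- (vals[1] - vals[2]) / zz
  if (eta < 0) {                       # swap x and y axes to make eta >= 0
    vals[1:2] <- vals[2:1]
    vecs[, 1:2] <- vecs[, 2:1]
    eta <- -eta
  }
  eta <- min(max(eta, 0), 1)
  if (det(vecs) < 0) vecs[, 1] <- -vecs[, 1]   # proper rotation
  quad_tensor(cq_hz * abs(zz), eta, euler_from_rot(vecs))
}

# ZYZ Euler angles from a proper rotation matrix (columns = new axes)
euler_from_rot <- function(R) {
  beta <- acos(min(max(R[3, 3], -1), 1))
  if (abs(sin(beta)) < 1e-10) {
    alpha <- atan2(R[2, 1], R[1, 1])
    if (R[3, 3] < 0) alpha <- -alpha
    return(c(alpha, if (R[3, 3] > 0) 0 else pi, 0))
  }
  alpha <- atan2(R[2, 3], R[1, 3])
  gamma <- atan2(R[3, 2], -R[3, 1])
  c(alpha, beta, gamma)
}
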