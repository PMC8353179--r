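# Independent oracles used across tests.  These deliberately avoid the
# package's internal rotation and superoperator helpers: rotations are built
# from scratch and frequencies evaluated through the static-angle formula.

o_rot_z <- function(a) {
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
o_rot_y <- function(b) {
  matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
}

# Cartesian PAS tensor (q_zz = 1) for asymmetry eta
o_pas <- function(eta) diag(c((eta - 1) / 2, -(eta + 1) / 2, 1))

# wQ under MAS by explicit frame composition: PAS -> crystallite (tensor
# euler, ZYZ active) -> rotor (Rz(-alpha) Ry(beta)) -> evaluate along the
# field direction seen in the rotor frame at time t,
# b(t) = (sin(tm) sin(wt), -sin(tm) cos(wt), cos(tm)), tm the magic angle.
oracle_wq_mas <- function(cq_hz, eta, tensor_euler, alpha, beta, t, omega_mas) {
  Rt <- o_rot_z(tensor_euler[1]) %*% o_rot_y(tensor_euler[2]) %*%
    o_rot_z(tensor_euler[3])
  Rc <- o_rot_z(-alpha) %*% o_rot_y(beta)
  A <- Rc %*% Rt %*% o_pas(eta) %*% t(Rt) %*% t(Rc)
  tm <- acos(1 / sqrt(3))
  vapply(t, function(tt) {
    wt <- omega_mas * tt
    b <- c(sin(tm) * sin(wt), -sin(tm) * cos(wt), cos(tm))
    (3 * pi / 2) * cq_hz * drop(b %*% A %*% b)
  }, numeric(1))
}

# conventional spin-1 operators built from raising/lowering, independent of
# spin1_operators()
oracle_spin1 <- function() {
  Ip <- matrix(c(0, sqrt(2), 0, 0, 0, sqrt(2), 0, 0, 0), 3, 3, byrow = TRUE)
  Im <- t(Ip)
  list(Ix = (Ip + Im) / 2, Iy = (Ip - Im) / (2i), Iz = diag(c(1, 0, -1)) + 0i,
       E = diag(3) + 0i)
}

# brute-force saturation propagation: sequential product of the same
# step-averaged substep exponentials over the whole interval, one at a time
# (no period powers, no caching) - isolates the power/fraction assembly
oracle_evolve <- function(network, params, orient, T_sat) {
  parts <- qcest:::liouvillian_parts(network, params, orient, 1)
  t_r <- 1 / params$omega_mas_hz
  dt <- t_r / params$n_rotor_steps
  n_full <- floor(T_sat / dt + 1e-9)
  v <- thermal_state(network)
  for (j in seq_len(n_full)) {
    L <- qcest:::liouvillian_cube(parts, (j - 1) * dt, dt, 1)[, , 1]
    v <- qcest:::cpp_expm(L * dt) %*% v
  }
  rem <- T_sat - n_full * dt
  if (rem > 1e-12 * t_r) {
    L <- qcest:::liouvillian_cube(parts, n_full * dt, rem, 1)[, , 1]
    v <- qcest:::cpp_expm(L * rem) %*% v
  }
  drop(v)
}

dms_flip_network <- function(k_flip = 9e3) {
  two_site_flip(55.3e3, 0, 106 * pi / 180, k_flip = k_flip)
}
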