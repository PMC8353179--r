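#' Secular spin-1 Hamiltonian
#'
#' Builds the 3x3 secular Hamiltonian during saturation.  In the tilted frame
#' (rotating with the RF carrier, x-axis along the RF field):
#' `H = sqrt(2/3) wQ Q + sqrt(2) wRF Sx + sqrt(2) W Sz`
#' with the trace-orthonormal operators of [spin_basis()].  The coefficients
#' are fixed so that `H` equals the conventional-operator construction
#' `(wQ/3)(3 Iz^2 - 2 E) + wRF Ix + W Iz`.  In the rotating frame the RF term
#' carries the time-dependent phase
#' `sqrt(2) wRF (Sx cos(W t) - Sy sin(W t))` and no offset term appears.
#'
#' @param omega_q secular quadrupolar frequency, rad/s.
#' @param omega_rf RF field strength, rad/s.
#' @param offset resonance offset Omega, rad/s (positive = carrier above the
#'   2H Larmor frequency).
#' @param frame `"tilted"` (default) or `"rotating"`.
#' @param t time (s), used only by the rotating frame.
#' @return complex Hermitian 3x3 matrix, rad/s.
#' @export
build_hamiltonian <- function(omega_q, omega_rf = 0, offset = 0,
                              frame = c("tilted", "rotating"), t = 0) {
  frame <- match.arg(frame)
  b <- spin_basis()
  H <- sqrt(2 / 3) * omega_q * b$Q
  if (frame == "tilted") {
    H <- H + sqrt(2) * omega_rf * b$Sx + sqrt(2) * offset * b$Sz
  } else {
    H <- H + sqrt(2) * omega_rf *
      (cos(offset * t) * b$Sx - sin(offset * t) * b$Sy)
  }
  H
}

#' Effective field during off-resonance irradiation
#'
#' `w_e = sqrt(wRF^2 + Omega^2)`, the magnitude of the effective field formed
#' by the RF field and the resonance offset in the rotating frame.
#'
#' @param omega_rf RF field strength, rad/s.
#' @param offset resonance offset, rad/s.
#' @return effective field, rad/s.
#' @examples
#' effective_field(2 * pi * 3e3, 2 * pi * 4e3) / (2 * pi)  # 5 kHz
#' @export
effective_field <- function(omega_rf, offset) sqrt(omega_rf^2 + offset^2)
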