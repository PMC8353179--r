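# Reduced Wigner matrix d^2_{m m'}(beta), indices m, m' = -2..2 mapped to
# rows/cols 1..5 (row 1 = m = -2).
wigner_d2 <- function(beta) {
  c <- cos(beta); s <- sin(beta)
  hp <- (1 + c) / 2; hm <- (1 - c) / 2
  q <- sqrt(3 / 8) * s^2; r <- sqrt(3 / 2) * s * c
  # rows m = -2..2 (top to bottom), cols m' = -2..2 (left to right)
  matrix(c(
    hp^2,     hp * s,  q,            hm * s,   hm^2,
    -hp * s,  (2*c - 1) * hp, r,     (2*c + 1) * hm, hm * s,
    q,        -r,      (3*c^2 - 1)/2, r,       q,
    -hm * s,  (2*c + 1) * hm, -r,    (2*c - 1) * hp, hp * s,
    hm^2,     -hm * s, q,            -hp * s,  hp^2
  ), 5, 5, byrow = TRUE)
}

# D^2_{m m'}(alpha, beta, gamma) = exp(-i m alpha) d^2_{m m'}(beta) exp(-i m' gamma)
wigner_D2 <- function(alpha, beta, gamma = 0) {
  m <- -2:2
  outer(exp(-1i * m * alpha), exp(-1i * m * gamma)) * wigner_d2(beta)
}

# Exchange-mode decomposition of the crystallite-frame autocorrelation
# functions C_{m'}(t) = <D^2_{m'0}(t) D^2*_{m'0}(0)> - static part, for a
# jump model with site orientations `eulers` (list of length-3), populations
# p and generator K.  Returns list(lambda = decay rates > 0,
# A = 5 x n_modes real amplitudes), so C_{m'}(t) = sum_r A[m', r] e^{-lambda_r t}.
# Cross-correlations between different m' do not enter powder-averaged rates:
# averaging over the crystallite's azimuth about its own z-axis (the third
# powder Euler angle) cancels them.
jump_correlation_modes <- function(eulers, p, K) {
  Dm0 <- vapply(eulers, function(e) wigner_D2(e[1], e[2], e[3])[, 3],
                complex(5))                       # 5 x n, column = site
  # symmetrized generator shares eigenvalues with K; detailed balance assumed
  S <- diag(1 / sqrt(p)) %*% K %*% diag(sqrt(p))
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- -eg$values
  keep <- which(lam > 1e-9 * max(lam, 1))
  if (length(keep) == 0) {
    return(list(lambda = numeric(0), A = matrix(0, 5, 0)))
  }
  A <- vapply(keep, function(k) {
    u <- eg$vectors[, k]
    # [e^{Kt}]_{ss'} p_{s'} = sum_k e^{-lam_k t} sqrt(p_s) u_s u_{s'} sqrt(p_{s'})
    abs(Dm0 %*% (sqrt(p) * u))^2
  }, numeric(5))
  list(lambda = lam[keep], A = matrix(A, nrow = 5))
}

#' Deuteron T1 from methyl three-site jumps
#'
#' Powder-averaged longitudinal relaxation time of a deuteron hopping among
#' three equivalent sites on a cone, from the quadrupolar spectral densities
#' at the Larmor frequency and twice it.  The rank-2 correlation functions
#' of the fluctuating tensor are evaluated exactly from the three-site jump
#' generator (eigenmode sums of exponentials); the orientation-dependent rate
#' `1/T1 = (3/80) chi^2 (J_1(w0) + 4 J_2(2 w0))`, `chi = 2 pi Cq`, is then
#' averaged over the powder.  The average over each crystallite's azimuth
#' about its own axis is analytic (it cancels the Wigner cross-terms),
#' leaving a sin(beta)-weighted average over the polar angle of the jump
#' axis (`method = "spectral"`, analytic Lorentzian spectral densities).
#' `method = "numeric"` instead integrates the correlation functions on a
#' dense time grid, an independent numerical route for cross-validation.
#'
#' @param cq_static_hz static (unaveraged) quadrupolar coupling, Hz.
#' @param k3 three-site jump rate constant, 1/s.
#' @param larmor_hz 2H Larmor frequency, Hz (92.1 MHz at 14.1 T,
#'   115.1 MHz at 17.6 T; see [deuteron_larmor_hz()]).
#' @param cone_angle cone half-angle, rad (tetrahedral by default).
#' @param powder_n powder orientations for the average.
#' @param method `"spectral"` (analytic) or `"numeric"` (quadrature oracle).
#' @return T1 in seconds (the inverse of the powder-averaged rate).
#' @export
t1_three_site_jumps <- function(cq_static_hz, k3, larmor_hz,
                                cone_angle = acos(-1 / 3), powder_n = 200,
                                method = c("spectral", "numeric")) {
  method <- match.arg(method)
  stopifnot(k3 > 0, larmor_hz > 0)
  eulers <- lapply(0:2, function(s) c(2 * pi * s / 3, cone_angle, 0))
  p <- rep(1 / 3, 3)
  K <- matrix(k3, 3, 3); diag(K) <- -2 * k3
  modes <- jump_correlation_modes(eulers, p, K)
  w0 <- 2 * pi * larmor_hz
  chi2 <- (2 * pi * cq_static_hz)^2
  # sin(beta)-weighted polar grid (azimuths already averaged analytically)
  cb <- (seq_len(powder_n) - 0.5) / powder_n * 2 - 1
  beta <- acos(cb)
  r1 <- vapply(beta, function(b) {
    d2 <- wigner_d2(b)
    j1 <- spectral_density_at(modes, d2, m = 1, w0, method)
    j2 <- spectral_density_at(modes, d2, m = 2, 2 * w0, method)
    (3 / 80) * chi2 * (j1 + 4 * j2)
  }, numeric(1))
  1 / mean(r1)
}

# J_m(w) = 2 Int_0^inf Chat_m(t) cos(wt) dt with the azimuth-averaged
# Chat_m(t; beta) = 5 sum_{m'} d^2_{mm'}(beta)^2 C_{m'}(t)
spectral_density_at <- function(modes, d2, m, w, method = "spectral") {
  row <- d2[m + 3L, ]^2                           # d^2_{m, m'} over m' = -2..2
  amp <- as.numeric(5 * (row %*% modes$A))        # one amplitude per mode
  if (method == "spectral") {
    sum(amp * 2 * modes$lambda / (modes$lambda^2 + w^2))
  } else {
    lam_min <- min(modes$lambda)
    t_max <- 40 / lam_min
    tt <- seq(0, t_max, length.out = 40000)
    Ct <- colSums(amp * exp(-outer(modes$lambda, tt)))
    2 * sum_trapz(tt, Ct * cos(w * tt))
  }
}

sum_trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Jump rate from a measured T1
#'
#' Inverts the [t1_three_site_jumps()] map on the fast-motion branch
#' (`3 k3 > w0`) by root finding: returns the `k3` whose predicted
#' powder-averaged T1 equals the measurement.
#'
#' @inheritParams t1_three_site_jumps
#' @param t1_s measured longitudinal relaxation time, s.
#' @param k3_max upper search bound, 1/s.
#' @return jump rate constant `k3`, 1/s.
#' @export
t1_to_k3 <- function(t1_s, cq_static_hz, larmor_hz,
                     cone_angle = acos(-1 / 3), powder_n = 200,
                     k3_max = 1e14) {
  w0 <- 2 * pi * larmor_hz
  k3_min <- w0 / 3                     # fast-branch edge: 3 k3 = w0
  f <- function(lk) {
    log(t1_three_site_jumps(cq_static_hz, 10^lk, larmor_hz, cone_angle,
                            powder_n)) - log(t1_s)
  }
  lo <- log10(k3_min); hi <- log10(k3_max)
  if (f(lo) * f(hi) > 0) {
    stop("no root in the fast-motion bracket [", signif(k3_min, 3), ", ",
         signif(k3_max, 3), "] 1/s for T1 = ", t1_s, " s")
  }
  10^stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Deuterium Larmor frequency
#'
#' Reference constants used throughout: 92.1 MHz at 14.1 T and 115.1 MHz at
#' 17.6 T (the two spectrometer fields of the CEST measurements); other
#' fields scale linearly from the 17.6 T anchor.
#'
#' @param field_t static field, Tesla.
#' @return Larmor frequency, Hz.
#' @export
deuteron_larmor_hz <- function(field_t) {
  if (isTRUE(all.equal(field_t, 14.1))) return(92.1e6)
  if (isTRUE(all.equal(field_t, 17.6))) return(115.1e6)
  field_t * (115.1e6 / 17.6)
}
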