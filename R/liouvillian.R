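#' Liouvillian of the saturation period
#'
#' Builds the full evolution generator on the direct-product space
#' {8 coherences} x {N sites}, augmented by one constant slot that carries
#' the inhomogeneous equilibrium-return term in homogeneous (matrix) form.
#' The state vector is site-major: entries `(i-1)*8 + (1..8)` are the
#' coherence coefficients of site `i` in the order of [spin_basis()], and the
#' last entry is the constant 1.
#'
#' The generator is the sum of
#' * the coherent part, block-diagonal over sites:
#'   `wQ_i(t) SQ + wRF SX + Omega SZ` per site (real antisymmetric);
#' * the exchange part `K (x) I_8`, coupling identical coherences across
#'   sites with the network's kinetic generator;
#' * optionally `-1/T1` on the chosen coherences plus the constant drive
#'   `+p_i/T1` returning each site's Zeeman order to its equilibrium value.
#'
#' @param network an [exchange_network()].
#' @param params an [experiment_params()].
#' @param orient a [crystallite()].
#' @param t time within the rotor period, s.
#' @param rf_scale multiplier on `omega_rf_hz` (RF-inhomogeneity grids).
#' @return real `(8N+1) x (8N+1)` matrix, 1/s.
#' @export
build_liouvillian <- function(network, params, orient, t = 0, rf_scale = 1) {
  parts <- liouvillian_parts(network, params, orient, rf_scale)
  liouvillian_at(parts, t)
}

# Precomputed time-independent pieces; wQ_i(t) is the only time dependence.
liouvillian_parts <- function(network, params, orient, rf_scale = 1) {
  so <- hamiltonian_superops()
  n <- length(network$sites)
  dim <- 8L * n + 1L
  w_rf <- 2 * pi * params$omega_rf_hz * rf_scale
  w_off <- 2 * pi * params$offset_hz
  p <- site_populations(network)

  Lstat <- matrix(0, dim, dim)
  idx8 <- seq_len(8L * n)
  Lstat[idx8, idx8] <- kronecker(network$rates, diag(8))
  block_const <- w_rf * so$SX + w_off * so$SZ
  for (i in seq_len(n)) {
    ii <- (i - 1L) * 8L + 1:8
    Lstat[ii, ii] <- Lstat[ii, ii] + block_const
  }
  if (!is.null(params$t1_s)) {
    r1 <- 1 / params$t1_s
    sz_idx <- (seq_len(n) - 1L) * 8L + 7L
    if (params$t1_mode == "all_coherences") {
      diag(Lstat)[idx8] <- diag(Lstat)[idx8] - r1
    } else {
      diag(Lstat)[sz_idx] <- diag(Lstat)[sz_idx] - r1
    }
    Lstat[sz_idx, dim] <- Lstat[sz_idx, dim] + r1 * p
  }

  wq_fun <- site_wq_functions(network, params, orient)
  list(Lstat = Lstat, SQ = so$SQ, n = n, dim = dim, wq_fun = wq_fun)
}

# per-site wQ(t) evaluators (rad/s); static crystallites use (theta = beta,
# phi = alpha) relative to the field
site_wq_functions <- function(network, params, orient) {
  w_mas <- 2 * pi * params$omega_mas_hz
  lapply(network$sites, function(s) {
    if (params$omega_mas_hz > 0) {
      function(t) quad_frequency_mas(s$tensor, orient, t, w_mas)
    } else {
      wq <- quad_frequency_static(s$tensor, orient$beta, orient$alpha)
      function(t) rep_len(wq, length(t))
    }
  })
}

liouvillian_at <- function(parts, t) {
  L <- parts$Lstat
  for (i in seq_len(parts$n)) {
    ii <- (i - 1L) * 8L + 1:8
    L[ii, ii] <- L[ii, ii] + parts$wq_fun[[i]](t) * parts$SQ
  }
  L
}

# cube of midpoint Liouvillians over [t0, t0 + duration] in n_steps equal
# steps: wQ(t) is held at its midpoint value within each step (the symmetric
# one-point rule; its per-step phase errors alternate in sign over a rotor
# period and largely cancel, which keeps 20 steps accurate even at slow
# spinning)
liouvillian_cube <- function(parts, t0, duration, n_steps) {
  dt <- duration / n_steps
  cube <- array(0, c(parts$dim, parts$dim, n_steps))
  for (j in seq_len(n_steps)) {
    cube[, , j] <- liouvillian_at(parts, t0 + (j - 0.5) * dt)
  }
  cube
}

#' Propagator for one MAS rotor period
#'
#' Time-ordered product of per-step matrix exponentials over a single rotor
#' period, with `wQ(t)` held at its midpoint value within each of
#' `n_rotor_steps` equal steps.  Coherent evolution, exchange and relaxation
#' are exponentiated together in each step (no splitting).
#'
#' @inheritParams build_liouvillian
#' @return real `(8N+1) x (8N+1)` propagator matrix.
#' @export
rotor_propagator <- function(network, params, orient, rf_scale = 1) {
  stopifnot(params$omega_mas_hz > 0)
  parts <- liouvillian_parts(network, params, orient, rf_scale)
  t_r <- 1 / params$omega_mas_hz
  cube <- liouvillian_cube(parts, 0, t_r, params$n_rotor_steps)
  cpp_step_prod(cube, t_r / params$n_rotor_steps)
}

# propagator over [0, duration] (duration < rotor period), same step rule:
# full substeps of the rotor grid, then one partial substep
partial_propagator <- function(parts, duration, t_r, n_steps) {
  if (duration <= 0) return(diag(parts$dim))
  dt <- t_r / n_steps
  n_full <- floor(duration / dt + 1e-9)
  U <- if (n_full > 0) {
    cpp_step_prod(liouvillian_cube(parts, 0, n_full * dt, n_full), dt)
  } else {
    diag(parts$dim)
  }
  rem <- duration - n_full * dt
  if (rem > 1e-12 * t_r) {
    Lrem <- liouvillian_cube(parts, n_full * dt, rem, 1)[, , 1]
    U <- cpp_expm(Lrem * rem) %*% U
  }
  U
}

#' Thermal-equilibrium density vector
#'
#' Starting state of the saturation period: only the Zeeman-order coefficient
#' of each site is populated, weighted by the site's equilibrium population
#' (total Zeeman order normalized to 1); the augmentation slot is 1.
#'
#' @param network an [exchange_network()].
#' @return numeric vector of length `8N + 1`.
#' @export
thermal_state <- function(network) {
  n <- length(network$sites)
  v <- numeric(8L * n + 1L)
  v[(seq_len(n) - 1L) * 8L + 7L] <- site_populations(network)
  v[8L * n + 1L] <- 1
  v
}

#' Total Zeeman order of a density vector
#'
#' Site sum of the Zeeman-order coefficients; equals the detected
#' all-bands signal amplitude after an ideal 90-degree read pulse.
#'
#' @param v density vector from [thermal_state()] / [evolve_saturation()].
#' @param network the matching [exchange_network()].
#' @return scalar.
#' @export
sz_total <- function(v, network) {
  n <- length(network$sites)
  sum(v[(seq_len(n) - 1L) * 8L + 7L])
}

#' Evolve through the saturation period
#'
#' Applies the rotor-period propagator to the whole number of rotor periods
#' within the saturation time and a fractional-rotation propagator (same
#' midpoint quadrature) for the remainder.  With `omega_mas_hz = 0` the
#' constant Liouvillian is exponentiated directly.
#'
#' @param rho0 starting density vector (e.g. [thermal_state()]).
#' @inheritParams build_liouvillian
#' @param u_rotor optional precomputed [rotor_propagator()] (cached by callers
#'   that scan saturation times).
#' @return evolved density vector.
#' @export
evolve_saturation <- function(rho0, network, params, orient, rf_scale = 1,
                              u_rotor = NULL) {
  T_sat <- params$sat_time_s
  if (T_sat <= 0) return(rho0)
  parts <- liouvillian_parts(network, params, orient, rf_scale)
  if (params$omega_mas_hz <= 0) {
    return(drop(cpp_expm(liouvillian_at(parts, 0) * T_sat) %*% rho0))
  }
  t_r <- 1 / params$omega_mas_hz
  m <- floor(T_sat / t_r + 1e-9)
  frac <- T_sat - m * t_r
  if (is.null(u_rotor)) {
    u_rotor <- cpp_step_prod(liouvillian_cube(parts, 0, t_r, params$n_rotor_steps),
                             t_r / params$n_rotor_steps)
  }
  v <- cpp_mat_pow(u_rotor, m) %*% rho0
  if (frac > 1e-12 * t_r) {
    v <- partial_propagator(parts, frac, t_r, params$n_rotor_steps) %*% v
  }
  drop(v)
}
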