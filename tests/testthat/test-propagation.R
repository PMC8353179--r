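test_that("coherent-only Liouvillian is antisymmetric and norm-preserving", {
  net <- single_site(55.3e3)
  p <- experiment_params(omega_rf_hz = 1.3e3, offset_hz = 10e3,
                         omega_mas_hz = 25e3, sat_time_s = 3e-3)
  or <- crystallite(0.7, 1.2)
  L <- build_liouvillian(net, p, or, t = 1.3e-5)
  C <- L[1:8, 1:8]
  expect_lt(max(abs(C + t(C))), 1e-9 * max(abs(C)))
  U <- rotor_propagator(net, p, or)
  set.seed(5)
  v <- c(stats::rnorm(8), 1)
  v1 <- U %*% v
  expect_lt(abs(sqrt(sum(v1[1:8]^2)) - sqrt(sum(v[1:8]^2))), 1e-10)
})

test_that("norm is conserved over 128 ms of coherent evolution", {
  net <- single_site(55.3e3)
  p <- experiment_params(omega_rf_hz = 1.3e3, offset_hz = 10e3,
                         omega_mas_hz = 25e3, sat_time_s = 3e-3)
  or <- crystallite(0.4, 0.9)
  U <- rotor_propagator(net, p, or)
  U128 <- qcest:::cpp_mat_pow(U, as.integer(0.128 * 25e3))
  v <- c(stats::rnorm(8), 1)
  expect_lt(abs(sqrt(sum((U128 %*% v)[1:8]^2)) - sqrt(sum(v[1:8]^2))), 1e-10)
})

test_that("exchange part of the Liouvillian is a generator on every coherence", {
  # a network with vanishing quadrupolar coupling isolates the exchange part
  net <- two_site_flip(0, 0, 106 * pi / 180, k_flip = 7e3)
  p <- experiment_params(omega_rf_hz = 0, offset_hz = 0, omega_mas_hz = 25e3,
                         sat_time_s = 0)
  L <- build_liouvillian(net, p, crystallite(0, 0.8), t = 0)
  blk <- L[1:16, 1:16]
  expect_equal(blk, kronecker(net$rates, diag(8)), tolerance = 1e-12)
  expect_lt(max(abs(colSums(blk))), 1e-9 * max(abs(net$rates)))
  # exchange couples identical coherences only
  for (coh in 1:8) {
    for (other in setdiff(1:8, coh)) {
      expect_identical(blk[coh, 8 + other], 0)
    }
  }
})

test_that("total Zeeman order is conserved without RF, even with exchange", {
  net <- dms_flip_network(9e3)
  p <- experiment_params(omega_rf_hz = 0, offset_hz = 10e3,
                         omega_mas_hz = 25e3, sat_time_s = 5e-3)
  or <- crystallite(1.0, 0.6)
  v <- evolve_saturation(thermal_state(net), net, p, or)
  expect_equal(sz_total(v, net), 1, tolerance = 1e-10)
})

test_that("phenomenological T1 relaxes Sz mono-exponentially to equilibrium", {
  net <- dms_flip_network(3e3)
  t1 <- 40e-3
  p <- experiment_params(omega_rf_hz = 0, offset_hz = 0, omega_mas_hz = 25e3,
                         sat_time_s = 7.3e-3, t1_s = t1)
  or <- crystallite(0.3, 1.0)
  rho <- thermal_state(net)
  start <- 0.25
  rho[c(7, 15)] <- start * site_populations(net)
  v <- evolve_saturation(rho, net, p, or)
  expected <- 1 + (start - 1) * exp(-p$sat_time_s / t1)
  expect_equal(sz_total(v, net), expected, tolerance = 1e-8)
  # sz_only mode gives the identical longitudinal behaviour at wRF = 0
  p2 <- experiment_params(omega_rf_hz = 0, offset_hz = 0, omega_mas_hz = 25e3,
                          sat_time_s = 7.3e-3, t1_s = t1, t1_mode = "sz_only")
  v2 <- evolve_saturation(rho, net, p2, or)
  expect_equal(sz_total(v2, net), expected, tolerance = 1e-8)
})

test_that("propagator powers compose exactly", {
  net <- single_site(55.3e3)
  p <- experiment_params(omega_rf_hz = 1.3e3, offset_hz = 12.5e3,
                         omega_mas_hz = 25e3, sat_time_s = 0)
  or <- crystallite(0.2, 1.3)
  U <- rotor_propagator(net, p, or)
  expect_equal(qcest:::cpp_mat_pow(U, 2), U %*% U, tolerance = 1e-14)
  # evolution over exactly 3 rotor periods is the propagator cubed
  p3 <- qcest:::modify_params(p, sat_time_s = 3 / 25e3)
  v <- evolve_saturation(thermal_state(net), net, p3, or, u_rotor = U)
  vref <- U %*% (U %*% (U %*% thermal_state(net)))
  expect_equal(v, drop(vref), tolerance = 1e-12)
})

test_that("beta = 0 collapses the rotor propagator to a single exponential", {
  net <- single_site(55.3e3)
  p <- experiment_params(omega_rf_hz = 1.3e3, offset_hz = 5e3,
                         omega_mas_hz = 25e3, sat_time_s = 0)
  or <- crystallite(0.9, 0)
  U <- rotor_propagator(net, p, or)
  L <- build_liouvillian(net, p, or, t = 0)
  expect_equal(U, qcest:::cpp_expm(L / 25e3), tolerance = 1e-10)
})

test_that("20-step quadrature agrees with finer quadratures", {
  net <- dms_flip_network(9e3)
  or <- crystallite(0.8, 1.1)
  p20 <- experiment_params(omega_rf_hz = 1.3e3, offset_hz = 10e3,
                           omega_mas_hz = 25e3, sat_time_s = 3e-3,
                           n_rotor_steps = 20)
  p100 <- qcest:::modify_params(p20, n_rotor_steps = 100L)
  U20 <- rotor_propagator(net, p20, or)
  U100 <- rotor_propagator(net, p100, or)
  expect_lt(max(abs(U20 - U100)), 1e-3)
  # saturation observable at 1 kHz MAS: 20 steps vs a 2000-step oracle.
  # At slow spinning the 20-step scheme is accurate at the few-per-mille
  # level (worst near rotary resonances); the profile shape is preserved.
  p1k <- experiment_params(omega_rf_hz = 1.3e3, offset_hz = 3e3,
                           omega_mas_hz = 1e3, sat_time_s = 2e-3,
                           n_rotor_steps = 20)
  p1k_fine <- qcest:::modify_params(p1k, n_rotor_steps = 2000L)
  v20 <- evolve_saturation(thermal_state(net), net, p1k, or)
  vf <- evolve_saturation(thermal_state(net), net, p1k_fine, or)
  expect_lt(abs(sz_total(v20, net) - sz_total(vf, net)), 5e-3)
})

test_that("period powers plus fractional rotation equal step-by-step integration", {
  net <- dms_flip_network(5e3)
  or <- crystallite(0.5, 0.9)
  for (T_sat in c(0, 1.37e-4, 3.1e-3)) {
    p <- experiment_params(omega_rf_hz = 1.3e3, offset_hz = 8e3,
                           omega_mas_hz = 25e3, sat_time_s = T_sat)
    v <- evolve_saturation(thermal_state(net), net, p, or)
    if (T_sat == 0) {
      expect_equal(v, thermal_state(net))
    } else {
      vref <- oracle_evolve(net, p, or, T_sat)
      expect_lt(max(abs(v - vref)), 1e-8)
    }
  }
})

test_that("static evolution uses the constant Liouvillian", {
  net <- single_site(55.3e3)
  p <- experiment_params(omega_rf_hz = 1.3e3, offset_hz = 20e3,
                         omega_mas_hz = 0, sat_time_s = 2e-3)
  or <- crystallite(0.4, 1.0)
  v <- evolve_saturation(thermal_state(net), net, p, or)
  parts <- qcest:::liouvillian_parts(net, p, or, 1)
  L <- qcest:::liouvillian_at(parts, 0)
  vref <- qcest:::cpp_expm(L * 2e-3) %*% thermal_state(net)
  expect_equal(v, drop(vref), tolerance = 1e-12)
})
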