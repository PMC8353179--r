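test_that("powder sets are normalized and isotropic", {
  tn <- quad_tensor(55.3e3)
  wq_scale <- (3 * pi / 2) * 55.3e3
  for (scheme in c("spiral", "golden", "grid")) {
    pw <- powder_orientations(3000, scheme)
    expect_equal(sum(pw$weight), 1, tolerance = 1e-12)
    expect_true(all(pw$beta >= 0 & pw$beta <= pi))
    wq <- quad_frequency_static(tn, pw$beta, pw$alpha)
    expect_lt(abs(sum(pw$weight * wq)), 1e-3 * wq_scale)
    # second moment: <P2^2> = 1/5 for an axial tensor
    m2 <- sum(pw$weight * wq^2)
    expect_lt(abs(m2 - wq_scale^2 / 5) / (wq_scale^2 / 5), 0.01)
  }
  expect_equal(nrow(powder_orientations(3000, "spiral")), 3000)
  expect_error(powder_orientations(10, "nope"))
})

test_that("powder mean of wQ vanishes for any tensor (tracelessness)", {
  pw <- powder_orientations(2000, "golden")
  for (eta in c(0, 0.4, 1)) {
    tn <- quad_tensor(90e3, eta, c(0.3, 0.8, 0.1))
    wq <- quad_frequency_static(tn, pw$beta, pw$alpha)
    expect_lt(abs(sum(pw$weight * wq)) / max(abs(wq)), 1e-3)
  }
  # the two-branch single-quantum spectrum (+wQ and -wQ lines) has zero odd
  # moments by construction
  tn <- quad_tensor(90e3)
  wq <- quad_frequency_static(tn, pw$beta, pw$alpha)
  expect_equal(sum(pw$weight * (wq^3 + (-wq)^3)) / 2, 0)
})

test_that("built-in probe grids match the measured six-point weights", {
  g13 <- rf_profile_builtin("bruker_1p3mm")
  g25 <- rf_profile_builtin("bruker_2p5mm")
  expect_equal(g13$scale, c(0.25, 0.5, 0.75, 1, 1.25, 1.5))
  expect_equal(sum(g13$weight), 1, tolerance = 1e-9)
  expect_equal(sum(g25$weight), 1, tolerance = 1e-9)
  # raw printed weights sum to ~1 before renormalization
  expect_equal(sum(c(0.084, 0.143, 0.126, 0.176, 0.285, 0.187)), 1.001,
               tolerance = 1e-9)
  expect_identical(g25$weight[6], 0)
})

test_that("30-point interpolation preserves the mean field scale", {
  for (nm in c("bruker_1p3mm", "bruker_2p5mm")) {
    p6 <- rf_profile_builtin(nm)
    p30 <- discretize_profile(p6, 30)
    expect_equal(nrow(p30), 30)
    m6 <- sum(p6$scale * p6$weight)
    m30 <- sum(p30$scale * p30$weight)
    expect_lt(abs(m30 - m6) / m6, 0.01)
  }
  expect_error(discretize_profile(rf_profile_builtin(), 12), "6 or 30")
})

test_that("nutation Fourier analysis recovers simple field distributions", {
  t <- seq(0, 4e-3, by = 1e-5)
  # single field: pure cosine at 10 kHz
  prof <- rf_profile_from_nutation(list(time_s = t, intensity = cos(2 * pi * 1e4 * t)))
  expect_equal(attr(prof, "mean_rf_hz"), 1e4, tolerance = 0.02)
  near1 <- abs(prof$scale - 1) < 0.15
  expect_gt(sum(prof$weight[near1]), 0.9)
  # two-component mixture: 60% at the mean-dominant field, 40% at 0.6 of it
  f0 <- 1e4
  y <- 0.6 * cos(2 * pi * f0 * t) + 0.4 * cos(2 * pi * 0.6 * f0 * t)
  prof2 <- rf_profile_from_nutation(list(time_s = t, intensity = y))
  mean_f <- attr(prof2, "mean_rf_hz")
  w_hi <- sum(prof2$weight[abs(prof2$scale * mean_f - f0) < 0.15 * f0])
  w_lo <- sum(prof2$weight[abs(prof2$scale * mean_f - 0.6 * f0) < 0.15 * f0])
  expect_lt(abs(w_hi - 0.6), 0.05)
  expect_lt(abs(w_lo - 0.4), 0.05)
  expect_error(rf_profile_from_nutation(list(time_s = c(0, 1e-5, 3e-5, 1e-4,
                                                        2e-4, 3e-4, 5e-4, 6e-4),
                                             intensity = rnorm(8))),
               "uniformly sampled")
})

test_that("profiles from different nominal powers collapse on the scale axis", {
  t <- seq(0, 4e-3, by = 1e-5)
  shape <- function(f0) {
    0.7 * cos(2 * pi * f0 * t) + 0.3 * cos(2 * pi * 0.5 * f0 * t)
  }
  p1 <- rf_profile_from_nutation(list(time_s = t, intensity = shape(8e3)))
  p2 <- rf_profile_from_nutation(list(time_s = t, intensity = shape(16e3)))
  # same shape versus wRF/<wRF>: compare coarse-grained distributions
  bin <- function(p) {
    vapply(seq(0.2, 1.6, by = 0.2), function(s) {
      sum(p$weight[abs(p$scale - s) <= 0.1])
    }, numeric(1))
  }
  expect_lt(max(abs(bin(p1) - bin(p2))), 0.05)
})

test_that("RF averaging is linear and exact for delta distributions", {
  delta <- rf_profile(1, 1, mean_rf_hz = 1.3e3)
  got <- average_over_rf(function(w) w^2, delta, mode = "grid",
                         offset_hz = 10e3)
  expect_equal(got, (1.3e3)^2)
  const <- average_over_rf(function(w) 0.42, rf_profile_builtin("bruker_1p3mm"),
                           mode = "grid", mean_rf_hz = 1.3e3, offset_hz = 10e3)
  expect_equal(const, 0.42, tolerance = 1e-12)
  g <- qcest:::rf_grid(NULL, "pm500", mean_rf_hz = 2.5e3)
  expect_equal(g$omega_rf_hz, 2.5e3 + c(-500, -250, 0, 250, 500))
  expect_equal(sum(g$weight), 1)
})

test_that("the dense 30-point grid is selected near zero offset", {
  p <- rf_profile_builtin("bruker_1p3mm")
  g_near <- qcest:::rf_grid(p, "grid", mean_rf_hz = 1.3e3, offset_hz = 1e3)
  g_far <- qcest:::rf_grid(p, "grid", mean_rf_hz = 1.3e3, offset_hz = 10e3)
  expect_gt(nrow(g_near), 20)
  expect_lte(nrow(g_far), 6)
})

test_that("inhomogeneity averaging weakens saturation at well-saturated offsets", {
  net <- dms_flip_network(1e4)
  p <- experiment_params(omega_rf_hz = 2.5e3, offset_hz = 0,
                         omega_mas_hz = 25e3, sat_time_s = 0)
  rfp <- rf_profile_builtin("bruker_2p5mm")
  off <- c(-20e3, 20e3)
  hom <- simulate_cest_profile(net, p, off, 20e-3, powder = 24)
  avg <- simulate_cest_profile(net, p, off, 20e-3, powder = 24,
                               rf_mode = "grid", rf_profile = rfp)
  # the homogeneous simulation overestimates the saturation
  expect_true(all(avg$intensity > hom$intensity))
  # averaged intensities remain within physical bounds
  expect_true(all(avg$intensity >= 0 & avg$intensity <= 1 + 1e-3))
})
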