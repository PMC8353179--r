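fit_design <- function() {
  list(params = experiment_params(omega_rf_hz = 1.3e3, offset_hz = 0,
                                  omega_mas_hz = 25e3, sat_time_s = 0),
       offsets = seq(-40e3, 40e3, by = 10e3),
       sat = c(3e-3, 20e-3),
       fixed = list(cq_eff_hz = 55.3e3, jump_angle = 106 * pi / 180),
       powder = 16)
}

test_that("self-fit of a noiseless profile attains zero objective", {
  d <- fit_design()
  truth <- simulate_cest_profile(dms_flip_network(9e3), d$params, d$offsets,
                                 d$sat, powder = d$powder)
  fit <- grid_search(truth, "two_site_flip", grid = list(k_flip = c(3e3, 9e3)),
                     fixed_args = d$fixed, params_list = list(d$params),
                     powder = d$powder)
  surf <- tidy(fit)
  expect_equal(surf$objective[surf$k_flip == 9e3], 0, tolerance = 1e-12)
  expect_gt(surf$objective[surf$k_flip == 3e3], 0)
  expect_equal(glance(fit)$k_flip, 9e3)
})

test_that("noisy synthetic data recover the generating flip rate", {
  d <- fit_design()
  fx <- make_fixture(dms_flip_network(9e3), d$params, d$offsets, d$sat,
                     noise_sigma = 0.01, seed = 21, powder = d$powder)
  fit <- grid_search(fx, "two_site_flip",
                     grid = list(k_flip = c(1, 3, 5, 7, 9, 12, 20) * 1e3),
                     fixed_args = d$fixed, params_list = list(d$params),
                     powder = d$powder)
  expect_true(glance(fit)$k_flip %in% c(7e3, 9e3, 12e3))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the objective is invariant under dataset order and padded offsets", {
  d <- fit_design()
  net <- dms_flip_network(9e3)
  prof1 <- simulate_cest_profile(net, d$params, d$offsets, 3e-3,
                                 powder = d$powder)
  prof2 <- simulate_cest_profile(net, d$params, d$offsets, 20e-3,
                                 powder = d$powder)
  grid <- list(k_flip = c(5e3, 9e3))
  f12 <- grid_search(list(prof1, prof2), "two_site_flip", grid,
                     fixed_args = d$fixed,
                     params_list = list(d$params, d$params), powder = d$powder)
  f21 <- grid_search(list(prof2, prof1), "two_site_flip", grid,
                     fixed_args = d$fixed,
                     params_list = list(d$params, d$params), powder = d$powder)
  expect_equal(tidy(f12)$objective, tidy(f21)$objective, tolerance = 1e-12)
  expect_equal(glance(f12)$k_flip, glance(f21)$k_flip)
})

test_that("per-dataset fits report one best node per dataset", {
  d <- fit_design()
  p1 <- simulate_cest_profile(dms_flip_network(5e3), d$params, d$offsets,
                              3e-3, powder = d$powder)
  p2 <- simulate_cest_profile(dms_flip_network(9e3), d$params, d$offsets,
                              3e-3, powder = d$powder)
  fit <- grid_search(list(p1, p2), "two_site_flip",
                     grid = list(k_flip = c(5e3, 9e3)), shared = "per_dataset",
                     fixed_args = d$fixed,
                     params_list = list(d$params, d$params), powder = d$powder)
  best <- glance(fit)
  expect_equal(nrow(best), 2)
  expect_equal(best$k_flip[best$dataset == 1], 5e3)
  expect_equal(best$k_flip[best$dataset == 2], 9e3)
})

test_that("ties break toward the smallest parameter values", {
  fake <- structure(list(
    surface = tibble::tibble(k_flip = c(9e3, 3e3, 5e3),
                             objective = c(0.1, 0.1, 0.2)),
    best = NULL, axes = "k_flip", shared = "global", n_datasets = 1),
    class = "cest_fit")
  tab <- dplyr::arrange(fake$surface, objective, k_flip)
  expect_equal(tab$k_flip[1], 3e3)
})

test_that("the ridge diagnostic traces the (D, k_ex) valley", {
  surf <- tidyr::expand_grid(D = c(1e6, 2e6, 4e6), k_ex = c(1e4, 3e4, 1e5))
  # construct a correlated valley: optimal k_ex grows with D
  surf$objective <- abs(log10(surf$k_ex) - (log10(surf$D) - 2))
  fit <- structure(list(surface = surf, best = NULL, axes = c("D", "k_ex"),
                        shared = "global", n_datasets = 1),
                   class = "cest_fit")
  ridge <- correlation_diagnostic(fit)
  expect_equal(nrow(ridge), 3)
  expect_true(all(diff(ridge$k_ex) >= 0))
  expect_false(attr(ridge, "degenerate"))
  # a single sharp minimum collapses the ridge to one optimum
  surf2 <- surf
  surf2$objective <- as.numeric(!(surf2$D == 2e6 & surf2$k_ex == 3e4))
  fit2 <- structure(list(surface = surf2, best = NULL, axes = c("D", "k_ex"),
                         shared = "global", n_datasets = 1),
                    class = "cest_fit")
  r2 <- correlation_diagnostic(fit2)
  expect_equal(r2$objective[r2$D == 2e6], 0)
  expect_error(correlation_diagnostic(structure(list(axes = "a"),
                                                class = "cest_fit")))
})

test_that("a reduced-scale fibril fit recovers a correlated (D, k_ex) ridge", {
  p <- experiment_params(omega_rf_hz = 1.3e3, offset_hz = 0,
                         omega_mas_hz = 25e3, sat_time_s = 0, t1_s = 50e-3)
  offs <- c(-20e3, -10e3, -4e3, 4e3, 10e3, 20e3)
  make_net <- function(D, k_ex) {
    sphere_diffusion_plus_bound(D, n_surface = 16, k_ex = k_ex,
                                p_bound = 0.08)
  }
  truth <- simulate_cest_profile(make_net(1.7e6, 3e4), p, offs, 20e-3,
                                 powder = 8)
  fit <- grid_search(truth, make_net,
                     grid = list(D = c(1e6, 1.7e6, 3e6),
                                 k_ex = c(1e4, 3e4, 1e5)),
                     params_list = list(p), powder = 8)
  best <- glance(fit)
  expect_equal(best$D, 1.7e6)
  expect_equal(best$k_ex, 3e4)
  ridge <- correlation_diagnostic(fit)
  expect_equal(nrow(ridge), 3)
})
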