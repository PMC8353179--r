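#' Offset sampling schedule
#'
#' Symmetric offset list over `+/- span_hz`: coarse spacing everywhere and
#' dense spacing within `dense_halfwidth_hz` of every rotary-resonance
#' position `+/- n * omega_mas/2` (integer and half-integer multiples of the
#' MAS rate), always including the exact resonance offsets and 0.
#'
#' @param omega_mas_hz MAS rate, Hz.
#' @param span_hz half-width of the scanned offset range, Hz.
#' @param coarse_hz coarse spacing, Hz.
#' @param dense_hz dense spacing near resonances, Hz.
#' @param dense_halfwidth_hz half-width of each dense region, Hz.
#' @return sorted numeric vector of offsets, Hz.
#' @export
offset_schedule <- function(omega_mas_hz, span_hz, coarse_hz = 2500,
                            dense_hz = 250, dense_halfwidth_hz = 1000) {
  stopifnot(coarse_hz > dense_hz, dense_hz > 0)
  if (span_hz < omega_mas_hz / 2) {
    stop("`span_hz` must reach at least the first rotary resonance (omega_mas/2)")
  }
  offs <- seq(0, span_hz, by = coarse_hz)
  res <- seq(omega_mas_hz / 2, span_hz, by = omega_mas_hz / 2)
  for (r in res) {
    lo <- max(0, r - dense_halfwidth_hz)
    offs <- c(offs, seq(lo, min(span_hz, r + dense_halfwidth_hz), by = dense_hz), r)
  }
  offs <- sort(unique(round(c(-offs, offs), 6)))
  offs
}

#' Simulate a CEST profile
#'
#' Full saturation-profile simulation: for every offset and saturation time,
#' the thermal state is propagated through the saturation period for each
#' crystallite orientation and RF-field grid node, the detected band
#' intensity is weight-averaged, and the result is divided by the matched
#' `T = 0` simulation run through the identical pipeline (same orientations,
#' same windows), so the profile reports `I(T)/I(0)`.
#'
#' `band_mode = "all_bands"` integrates the whole sideband family, which
#' equals the total detected Zeeman order (discrete Parseval identity) and is
#' evaluated directly from the post-saturation state; `"central"` runs the
#' detection block and integrates the centre-band window only.
#'
#' @param network an [exchange_network()].
#' @param params an [experiment_params()] (its `offset_hz`/`sat_time_s` are
#'   overridden by the scanned values).
#' @param offsets_hz offsets to scan, Hz.
#' @param sat_times_s saturation times, s.
#' @param band_mode `"all_bands"` or `"central"`.
#' @param powder number of orientations (spiral scheme) or a
#'   [powder_orientations()] tibble.
#' @param rf_mode RF averaging mode, see [average_over_rf()].
#' @param rf_profile an [rf_profile()] for `rf_mode = "grid"`.
#' @param lb_hz apodization for central-band detection, Hz.
#' @return tibble of class `cest_profile` with columns `offset_hz`,
#'   `sat_time_s`, `intensity`, and a `meta` attribute echoing the setup.
#' @export
simulate_cest_profile <- function(network, params, offsets_hz, sat_times_s,
                                  band_mode = c("all_bands", "central"),
                                  powder = 100,
                                  rf_mode = c("none", "grid", "pm500"),
                                  rf_profile = NULL, lb_hz = 100) {
  band_mode <- match.arg(band_mode)
  rf_mode <- match.arg(rf_mode)
  if (is.numeric(powder)) powder <- powder_orientations(powder)
  orients <- as_crystallites(powder)
  sat <- as.numeric(sat_times_s)
  offs <- as.numeric(offsets_hz)
  t_r <- if (params$omega_mas_hz > 0) 1 / params$omega_mas_hz else Inf
  v0 <- thermal_state(network)

  intensity <- matrix(0, length(offs), length(sat))
  for (io in seq_along(offs)) {
    p_off <- modify_params(params, offset_hz = offs[io])
    grid <- rf_grid(rf_profile, rf_mode, mean_rf_hz = params$omega_rf_hz,
                    offset_hz = offs[io])
    num <- matrix(0, 1, length(sat)); den <- 0
    for (orient in orients) {
      if (band_mode == "central") {
        den <- den + orient$weight *
          central_intensity(v0, network, p_off, orient, lb_hz)
      } else {
        den <- den + orient$weight   # thermal all-bands intensity is 1
      }
      for (ig in seq_len(nrow(grid))) {
        rf_scale <- if (params$omega_rf_hz > 0) {
          grid$omega_rf_hz[ig] / params$omega_rf_hz
        } else 1
        parts <- liouvillian_parts(network, p_off, orient, rf_scale)
        states <- saturation_states(parts, v0, sat, t_r, params$n_rotor_steps)
        w <- orient$weight * grid$weight[ig]
        for (it in seq_along(sat)) {
          val <- if (band_mode == "all_bands") {
            sz_total(states[[it]], network)
          } else {
            central_intensity(states[[it]], network, p_off, orient, lb_hz)
          }
          num[1, it] <- num[1, it] + w * val
        }
      }
    }
    intensity[io, ] <- num[1, ] / den
  }

  ord <- order(offs)
  out <- tidyr::expand_grid(offset_hz = offs[ord], sat_time_s = sat)
  out$intensity <- as.vector(t(intensity[ord, , drop = FALSE]))
  attr(out, "meta") <- list(band_mode = band_mode, rf_mode = rf_mode,
                            powder_n = nrow(powder), params = params,
                            n_sites = length(network$sites), lb_hz = lb_hz)
  class(out) <- c("cest_profile", class(out))
  out
}

# post-saturation states for a set of saturation times, sharing the
# rotor-period propagator
saturation_states <- function(parts, v0, sat_times, t_r, n_steps) {
  if (!is.finite(t_r)) {                 # static: constant Liouvillian
    L <- liouvillian_at(parts, 0)
    return(lapply(sat_times, function(T) {
      if (T <= 0) v0 else drop(cpp_expm(L * T) %*% v0)
    }))
  }
  U <- cpp_step_prod(liouvillian_cube(parts, 0, t_r, n_steps), t_r / n_steps)
  lapply(sat_times, function(T) {
    if (T <= 0) return(v0)
    m <- floor(T / t_r + 1e-9)
    v <- cpp_mat_pow(U, m) %*% v0
    frac <- T - m * t_r
    if (frac > 1e-12 * t_r) {
      v <- partial_propagator(parts, frac, t_r, n_steps) %*% v
    }
    drop(v)
  })
}

central_intensity <- function(v, network, params, orient, lb_hz) {
  fid <- detect_fid(v, network, params, orient)
  integrate_bands(fid, params$omega_mas_hz, lb_hz = lb_hz)$central
}

#' Saturation decay rate R_CEST at one offset
#'
#' Simulates the all-bands intensity versus saturation time at a fixed
#' offset and fits a single exponential `A exp(-R T)` by least squares.
#' Fast relaxation pathways produce visibly non-exponential decays; the
#' result is flagged when the relative fit rms exceeds 5%.
#'
#' @inheritParams simulate_cest_profile
#' @param offset_hz single offset, Hz.
#' @param t_grid_s saturation-time grid, s, within 0.25-128 ms.
#' @return object of class `rcest_result`: `rate` (1/s), `amplitude`,
#'   `rms_rel`, `nonexponential`, and the decay data.
#' @export
rcest <- function(network, params, offset_hz,
                  t_grid_s = c(0.25, 0.5, 1, 2, 4, 8, 16, 32, 64, 128) * 1e-3,
                  powder = 100, rf_mode = "none", rf_profile = NULL) {
  stopifnot(all(t_grid_s >= 0.25e-3 - 1e-12), all(t_grid_s <= 128e-3 + 1e-12))
  prof <- simulate_cest_profile(network, params, offset_hz, t_grid_s,
                                band_mode = "all_bands", powder = powder,
                                rf_mode = rf_mode, rf_profile = rf_profile)
  fit_rcest_decay(prof$sat_time_s, prof$intensity)
}

#' Fit a mono-exponential to a saturation decay
#'
#' @param t saturation times, s.
#' @param intensity normalized intensities (must be positive).
#' @return an `rcest_result`.
#' @export
fit_rcest_decay <- function(t, intensity) {
  if (any(intensity <= 0)) stop("non-positive intensities in decay curve")
  ord <- order(t)
  t <- t[ord]; I <- intensity[ord]
  if (stats::sd(I) < 1e-12) {
    fitted <- rep(mean(I), length(I))
    res <- list(rate = 0, amplitude = mean(I))
  } else {
    cf <- stats::coef(stats::lm(log(I) ~ t))
    start <- list(A = exp(unname(cf[1])), R = max(-unname(cf[2]), 0))
    fit <- tryCatch(
      stats::nls(I ~ A * exp(-R * t), start = start,
                 control = stats::nls.control(maxiter = 500, tol = 1e-12,
                                              minFactor = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) {
      obj <- function(p) sum((I - p[1] * exp(-p[2] * t))^2)
      op <- stats::optim(c(start$A, start$R), obj, method = "L-BFGS-B",
                         lower = c(1e-12, 0), upper = c(10, 1e12))
      res <- list(rate = op$par[2], amplitude = op$par[1])
    } else {
      cf <- stats::coef(fit)
      res <- list(rate = max(unname(cf["R"]), 0), amplitude = unname(cf["A"]))
    }
    fitted <- res$amplitude * exp(-res$rate * t)
  }
  rms <- sqrt(mean((I - fitted)^2)) / mean(I)
  structure(list(rate = res$rate, amplitude = res$amplitude, rms_rel = rms,
                 nonexponential = rms > 0.05,
                 data = tibble::tibble(sat_time_s = t, intensity = I)),
            class = "rcest_result")
}

#' @export
print.rcest_result <- function(x, ...) {
  cat(sprintf("<rcest_result> R_CEST = %.4g 1/s, A = %.4g, rel. rms = %.2g%s\n",
              x$rate, x$amplitude, x$rms_rel,
              if (x$nonexponential) " [non-exponential]" else ""))
  invisible(x)
}
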