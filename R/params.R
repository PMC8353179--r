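#' Experiment parameters
#'
#' Acquisition and saturation settings for a CEST simulation.  All interface
#' frequencies are in Hz (the engine converts to rad/s internally).
#'
#' @param omega_rf_hz mean saturation field strength `<wRF>/2pi`, Hz.
#' @param offset_hz resonance offset `Omega/2pi`, Hz (positive = carrier above
#'   the 2H Larmor frequency).
#' @param omega_mas_hz MAS rate `wMAS/2pi`, Hz; `0` selects static evolution.
#' @param sat_time_s saturation time `T`, s.
#' @param t1_s optional phenomenological longitudinal time constant, s
#'   (`NULL` disables relaxation).
#' @param t1_mode `"all_coherences"` applies `-1/T1` to all eight coherences
#'   of every site (with the Zeeman order driven back to its site equilibrium,
#'   the Bloch-McConnell-style inhomogeneous term); `"sz_only"` restricts
#'   relaxation to the Zeeman order.
#' @param n_rotor_steps quadrature steps per MAS rotor period (>= 4).
#' @param dwell_s detection dwell time, s.
#' @param n_points number of detected FID points.
#' @return Object of class `experiment_params`.
#' @export
experiment_params <- function(omega_rf_hz, offset_hz = 0, omega_mas_hz,
                              sat_time_s, t1_s = NULL,
                              t1_mode = c("all_coherences", "sz_only"),
                              n_rotor_steps = 20,
                              dwell_s = 2e-6, n_points = 1024) {
  t1_mode <- match.arg(t1_mode)
  stopifnot(omega_rf_hz >= 0, omega_mas_hz >= 0, sat_time_s >= 0,
            n_rotor_steps >= 4, dwell_s > 0, n_points >= 2)
  if (!is.null(t1_s)) stopifnot(t1_s > 0)
  structure(list(omega_rf_hz = omega_rf_hz, offset_hz = offset_hz,
                 omega_mas_hz = omega_mas_hz, sat_time_s = sat_time_s,
                 t1_s = t1_s, t1_mode = t1_mode,
                 n_rotor_steps = as.integer(n_rotor_steps),
                 dwell_s = dwell_s, n_points = as.integer(n_points)),
            class = "experiment_params")
}

#' @export
print.experiment_params <- function(x, ...) {
  cat(sprintf(
    "<experiment_params> wRF/2pi = %.4g kHz, offset = %.4g kHz, MAS = %.4g kHz, T = %.4g ms, T1 = %s\n",
    x$omega_rf_hz / 1e3, x$offset_hz / 1e3, x$omega_mas_hz / 1e3,
    x$sat_time_s * 1e3,
    if (is.null(x$t1_s)) "none" else sprintf("%.3g ms (%s)", x$t1_s * 1e3, x$t1_mode)))
  invisible(x)
}

# convenience: copy with modified fields
modify_params <- function(params, ...) {
  mods <- list(...)
  for (nm in names(mods)) params[[nm]] <- mods[[nm]]
  params
}
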