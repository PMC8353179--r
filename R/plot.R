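#' Plot a CEST profile
#'
#' Normalized intensity versus offset (kHz), one curve per saturation time.
#'
#' @param object a `cest_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cest_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$offset_hz / 1e3, y = .data$intensity,
                               colour = factor(.data$sat_time_s * 1e3))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Omega / 2 * pi ~ "(kHz)"),
                  y = "I(T)/I(0)", colour = "T (ms)") +
    ggplot2::theme_minimal()
}

#' Plot an R_CEST decay and its mono-exponential fit
#'
#' @param object an `rcest_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rcest_result <- function(object, ...) {
  d <- tidy.rcest_result(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sat_time_s * 1e3)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(x = "T (ms)", y = "I(T)/I(0)",
                  subtitle = sprintf("R_CEST = %.3g 1/s%s", object$rate,
                                     if (object$nonexponential)
                                       " (non-exponential)" else "")) +
    ggplot2::theme_minimal()
}

#' Plot a grid-search objective surface
#'
#' A line plot for 1-D grids, a raster for 2-D grids (log10 axes when the
#' grid spans more than a decade).
#'
#' @param object a `cest_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cest_fit <- function(object, ...) {
  surf <- object$surface
  a <- object$axes
  if (length(a) == 1) {
    p <- ggplot2::ggplot(surf, ggplot2::aes(x = .data[[a]],
                                            y = .data$objective)) +
      ggplot2::geom_line() + ggplot2::geom_point()
    if (max(surf[[a]]) / max(min(surf[[a]]), 1e-300) > 10) {
      p <- p + ggplot2::scale_x_log10()
    }
  } else {
    p <- ggplot2::ggplot(surf, ggplot2::aes(x = .data[[a[1]]],
                                            y = .data[[a[2]]],
                                            fill = .data$objective)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(direction = -1)
  }
  p + ggplot2::labs(y = if (length(a) == 1) "mean |dI|" else a[2]) +
    ggplot2::theme_minimal()
}
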