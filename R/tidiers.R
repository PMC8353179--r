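#' Tidy a grid-search fit
#'
#' One row per grid node (per dataset for per-dataset fits) with the mean
#' absolute difference objective.
#'
#' @param x a `cest_fit` from [grid_search()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.cest_fit <- function(x, ...) x$surface

#' Glance at a grid-search fit
#'
#' The best node(s) with the attained objective.
#'
#' @inheritParams tidy.cest_fit
#' @return a one-row (global) or one-row-per-dataset tibble.
#' @export
glance.cest_fit <- function(x, ...) x$best

#' Tidy an R_CEST decay fit
#'
#' @param x an `rcest_result` from [rcest()].
#' @param ... unused.
#' @return tibble of the decay points with the fitted curve and residuals.
#' @export
tidy.rcest_result <- function(x, ...) {
  d <- x$data
  d$fitted <- x$amplitude * exp(-x$rate * d$sat_time_s)
  d$residual <- d$intensity - d$fitted
  d
}

#' Glance at an R_CEST decay fit
#'
#' @inheritParams tidy.rcest_result
#' @return one-row tibble: `rate`, `amplitude`, `rms_rel`, `nonexponential`.
#' @export
glance.rcest_result <- function(x, ...) {
  tibble::tibble(rate = x$rate, amplitude = x$amplitude,
                 rms_rel = x$rms_rel, nonexponential = x$nonexponential)
}
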