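#' Grid-search fit of CEST profiles
#'
#' Simulates the chosen motional model on a grid of parameter values and
#' scores every node by the mean absolute difference between measured and
#' simulated normalized intensities, pooled over all `(offset, sat_time)`
#' points of a dataset and, for a global fit, averaged over datasets.  The
#' whole objective surface is returned: for slow-motion models the minima
#' are typically shallow and the surface, not only the argmin, carries the
#' information (in particular the correlated (D, k_ex) valley of the
#' sphere-diffusion model, see [correlation_diagnostic()]).
#'
#' Simulated profiles are evaluated at each dataset's offsets; when a
#' simulation is supplied on a different offset grid it is matched by
#' nearest neighbour within 50 Hz, else by linear interpolation.  Ties in
#' the objective are broken toward the smallest parameter values
#' (lexicographic over the grid axes in order).
#'
#' @param datasets a `cest_profile` (or list of them), each with columns
#'   `offset_hz`, `sat_time_s`, `intensity`; the simulation settings are
#'   taken from each dataset's `meta` attribute unless `params_list` is given.
#' @param model_fn function mapping one named grid node (plus `fixed_args`)
#'   to an [exchange_network()], or a model name for [build_exchange_model()].
#' @param grid named list of parameter axes, e.g.
#'   `list(k_flip = c(3e3, 9e3, 3e4))` or `list(D = ..., k_ex = ...)`.
#' @param shared `"global"` (one objective, averaged over datasets) or
#'   `"per_dataset"` (independent argmin per dataset).
#' @param offsets_subset optional offsets (Hz) to restrict the comparison to.
#' @param fixed_args named list of model arguments common to all nodes.
#' @param params_list optional list of [experiment_params()] per dataset.
#' @param powder,rf_mode,rf_profile,band_mode forwarded to
#'   [simulate_cest_profile()].
#' @param use_cache reuse simulated node profiles across calls with identical
#'   settings (simulation dominates the cost of repeated fits, e.g. of noise
#'   replicates against one grid).
#' @return object of class `cest_fit`: tibble `surface` (one row per node
#'   (x dataset)), `best` node(s), and the grid axes.
#' @export
grid_search <- function(datasets, model_fn, grid,
                        shared = c("global", "per_dataset"),
                        offsets_subset = NULL, fixed_args = list(),
                        params_list = NULL, powder = 100,
                        rf_mode = "none", rf_profile = NULL,
                        band_mode = NULL, use_cache = TRUE) {
  shared <- match.arg(shared)
  if (inherits(datasets, "cest_profile") || is.data.frame(datasets)) {
    datasets <- list(datasets)
  }
  stopifnot(length(grid) >= 1, !is.null(names(grid)))
  if (is.character(model_fn)) {
    model_name <- model_fn
    model_tag <- model_name
    model_fn <- function(...) build_exchange_model(model_name,
                                                   c(list(...), fixed_args))
  } else {
    user_fn <- model_fn
    model_tag <- paste(deparse(user_fn), collapse = "")
    model_fn <- function(...) do.call(user_fn, c(list(...), fixed_args))
  }

  band_modes <- vapply(datasets, function(d) {
    m <- attr(d, "meta")
    if (!is.null(band_mode)) band_mode
    else if (!is.null(m$band_mode)) m$band_mode else "all_bands"
  }, character(1))
  if (length(unique(band_modes)) > 1) {
    stop("datasets mix band modes; fit them separately or set `band_mode`")
  }

  nodes <- do.call(tidyr::expand_grid, grid)
  axes <- names(grid)
  rows <- list()
  for (k in seq_len(nrow(nodes))) {
    node <- as.list(nodes[k, , drop = FALSE])
    network <- do.call(model_fn, node)
    for (id in seq_along(datasets)) {
      d <- datasets[[id]]
      pars <- if (!is.null(params_list)) params_list[[id]] else {
        attr(d, "meta")$params
      }
      if (is.null(pars)) stop("dataset ", id, " carries no simulation params")
      pts <- d
      if (!is.null(offsets_subset)) {
        keep <- vapply(pts$offset_hz,
                       function(o) any(abs(o - offsets_subset) <= 50), logical(1))
        pts <- pts[keep, , drop = FALSE]
      }
      sim_offsets <- sort(unique(pts$offset_hz))
      sim_sat <- sort(unique(pts$sat_time_s))
      key <- paste(c(model_tag, names(node), unlist(node),
                     names(fixed_args), unlist(fixed_args), sim_offsets,
                     sim_sat, band_modes[1],
                     if (is.numeric(powder)) powder else nrow(powder),
                     rf_mode, pars$omega_rf_hz, pars$omega_mas_hz,
                     pars$t1_s, pars$t1_mode, pars$n_rotor_steps),
                   collapse = "|")
      sim <- if (use_cache && !is.null(.qcest_cache$sims[[key]])) {
        .qcest_cache$sims[[key]]
      } else {
        s <- simulate_cest_profile(network, pars,
                                   offsets_hz = sim_offsets,
                                   sat_times_s = sim_sat,
                                   band_mode = band_modes[1], powder = powder,
                                   rf_mode = rf_mode, rf_profile = rf_profile)
        if (use_cache) {
          if (is.null(.qcest_cache$sims)) .qcest_cache$sims <- list()
          .qcest_cache$sims[[key]] <- s
        }
        s
      }
      isim <- match_profile(sim, pts)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        !!!node, dataset = id,
        objective = mean(abs(pts$intensity - isim)))
    }
  }
  surface <- dplyr::bind_rows(rows)

  pick_best <- function(tab) {
    tab <- dplyr::arrange(tab, .data$objective,
                          !!!rlang::syms(axes))   # deterministic tie-break
    tab[1, , drop = FALSE]
  }
  if (shared == "global") {
    pooled <- dplyr::summarise(dplyr::group_by(surface,
                                               !!!rlang::syms(axes)),
                               objective = mean(.data$objective),
                               .groups = "drop")
    best <- pick_best(pooled)
    surface_out <- pooled
  } else {
    best <- dplyr::bind_rows(lapply(split(surface, surface$dataset), pick_best))
    surface_out <- surface
  }
  structure(list(surface = surface_out, best = best, axes = axes,
                 shared = shared, n_datasets = length(datasets)),
            class = "cest_fit")
}

# look up simulated intensities at the (offset, sat_time) points of `pts`:
# nearest simulated offset within 50 Hz, else linear interpolation
match_profile <- function(sim, pts) {
  vapply(seq_len(nrow(pts)), function(i) {
    s <- sim[abs(sim$sat_time_s - pts$sat_time_s[i]) < 1e-12, , drop = FALSE]
    if (nrow(s) == 0) stop("saturation time ", pts$sat_time_s[i],
                           " s missing from the simulation")
    dist <- abs(s$offset_hz - pts$offset_hz[i])
    j <- which.min(dist)
    if (dist[j] <= 50) {
      s$intensity[j]
    } else {
      stats::approx(s$offset_hz, s$intensity, xout = pts$offset_hz[i],
                    rule = 1)$y
    }
  }, numeric(1))
}

#' @export
print.cest_fit <- function(x, ...) {
  cat(sprintf("<cest_fit> %s fit over %d node(s), axes: %s\n",
              x$shared, nrow(x$surface), paste(x$axes, collapse = ", ")))
  print(x$best)
  invisible(x)
}

#' Ridge of the (D, k_ex) objective surface
#'
#' For every value of the first grid axis, the value of the second axis that
#' minimizes the objective.  A monotone ridge exposes the positive
#' correlation between diffusion coefficient and exchange rate: fast
#' diffusion narrows the CEST pattern while slow conformational exchange
#' widens it, so the two trade off along a valley of comparable fits.
#'
#' @param result a `cest_fit` over a 2-D grid.
#' @return tibble with one row per first-axis value: the minimizing second
#'   axis value and the objective; attribute `degenerate` is `TRUE` when the
#'   surface is flat.
#' @export
correlation_diagnostic <- function(result) {
  stopifnot(inherits(result, "cest_fit"))
  if (length(result$axes) != 2) stop("ridge diagnostic needs a 2-D grid")
  a1 <- result$axes[1]; a2 <- result$axes[2]
  surf <- result$surface
  if (result$shared == "per_dataset") {
    surf <- dplyr::summarise(dplyr::group_by(surf, !!!rlang::syms(result$axes)),
                             objective = mean(.data$objective), .groups = "drop")
  }
  ridge <- dplyr::bind_rows(lapply(split(surf, surf[[a1]]), function(tab) {
    tab <- dplyr::arrange(tab, .data$objective, !!rlang::sym(a2))
    tab[1, c(a1, a2, "objective")]
  }))
  ridge <- dplyr::arrange(ridge, !!rlang::sym(a1))
  attr(ridge, "degenerate") <-
    (max(surf$objective) - min(surf$objective)) < 1e-12
  ridge
}
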