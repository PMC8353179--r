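#' Exchange network of quadrupolar sites
#'
#' An exchange network couples `N` sites, each carrying a quadrupolar tensor
#' orientation and an equilibrium population, through a first-order kinetic
#' rate matrix `K` in generator (column) convention: `K[i, j]` is the rate
#' from site `j` to site `i` (1/s), diagonals close every column to zero, so
#' `dp/dt = K p` and `K p_eq = 0`.
#'
#' @param sites list of sites, each a list with elements `tensor`
#'   (a [quad_tensor()]) and `population`.
#' @param rates N x N rate matrix, generator convention, 1/s.
#' @return Object of class `exchange_network`.
#' @export
exchange_network <- function(sites, rates) {
  n <- length(sites)
  stopifnot(is.matrix(rates), nrow(rates) == n, ncol(rates) == n)
  p <- vapply(sites, function(s) s$population, numeric(1))
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8)
  if (any(rates[row(rates) != col(rates)] < -1e-12)) {
    stop("off-diagonal rates must be non-negative")
  }
  if (max(abs(colSums(rates))) > 1e-8 * max(1, max(abs(rates)))) {
    stop("columns of the rate matrix must sum to zero")
  }
  structure(list(sites = sites, rates = rates), class = "exchange_network")
}

#' @export
print.exchange_network <- function(x, ...) {
  cat(sprintf("<exchange_network> %d sites, max |rate| = %.3g 1/s\n",
              length(x$sites), max(abs(x$rates))))
  invisible(x)
}

#' @rdname exchange_network
#' @param network an `exchange_network`.
#' @export
site_populations <- function(network) {
  vapply(network$sites, function(s) s$population, numeric(1))
}

new_site <- function(tensor, population) list(tensor = tensor, population = population)

#' Two-site flip model
#'
#' Two sites whose tensor z-axes subtend `jump_angle`, exchanging by a slow
#' flip.  For equal populations both inter-site rates equal `k_flip` and the
#' total exchange rate constant is `k_ex = 2 k_flip` (`k_ex` = sum of forward
#' and reverse rates throughout this package).  For unequal populations the
#' rates are `k(1 -> 2) = k_ex p2`, `k(2 -> 1) = k_ex p1`, which satisfies
#' detailed balance.  This is the rotameric-flip model of dimethyl-sulfone
#' (effective methyl-averaged `Cq` of 55.3 kHz, jump angle 106 deg).
#'
#' @param cq_eff_hz effective (fast-motion-averaged) `Cq` of both sites, Hz.
#' @param eta asymmetry of both sites.
#' @param jump_angle angle between the two tensor z-axes, rad.
#' @param k_flip flip rate constant, 1/s (`k_ex = 2 k_flip`).
#' @param populations length-2 equilibrium populations summing to 1.
#' @return an [exchange_network()].
#' @export
two_site_flip <- function(cq_eff_hz, eta = 0, jump_angle = 106 * pi / 180,
                          k_flip, populations = c(0.5, 0.5)) {
  stopifnot(length(populations) == 2, all(populations > 0))
  if (abs(sum(populations) - 1) > 1e-8) stop("populations must sum to 1")
  sites <- list(
    new_site(quad_tensor(cq_eff_hz, eta, c(0,  jump_angle / 2, 0)), populations[1]),
    new_site(quad_tensor(cq_eff_hz, eta, c(0, -jump_angle / 2, 0)), populations[2])
  )
  k_ex <- 2 * k_flip
  k12 <- k_ex * populations[2]   # rate 1 -> 2
  k21 <- k_ex * populations[1]   # rate 2 -> 1
  K <- matrix(c(-k12, k12, k21, -k21), 2, 2)
  exchange_network(sites, K)
}

#' Methyl three-site jump model
#'
#' Three equally populated sites at 120 deg azimuthal spacing on a cone of
#' `cone_angle` about the methyl rotation axis, all inter-site jump rates
#' `k3`.  In the fast limit the exchange-averaged tensor equals
#' [average_tensor_fast_rotation()] of the static tensor.
#'
#' @param cq_static_hz static (unaveraged) `Cq`, Hz.
#' @param k3 jump rate constant between any pair of sites, 1/s.
#' @param cone_angle cone half-angle, rad; default the tetrahedral angle.
#' @param eta site asymmetry.
#' @return an [exchange_network()].
#' @export
methyl_three_site <- function(cq_static_hz, k3, cone_angle = acos(-1 / 3),
                              eta = 0) {
  stopifnot(k3 >= 0)
  sites <- lapply(0:2, function(k) {
    new_site(quad_tensor(cq_static_hz, eta, c(2 * pi * k / 3, cone_angle, 0)),
             1 / 3)
  })
  K <- matrix(k3, 3, 3); diag(K) <- -2 * k3
  exchange_network(sites, K)
}

#' Sphere diffusion plus bound state model
#'
#' Discrete model of a side chain whose free state reorients by isotropic
#' rotational diffusion (coefficient `D`, rad^2/s) over `n_surface`
#' near-uniform directions on the sphere, in slow exchange with a single
#' rigid bound state.  Surface sites carry the (methyl-averaged) tensor with
#' z-axis along the site direction and share population `(1 - p_bound)`.
#' Inter-site diffusion uses nearest-neighbour rates weighted by inverse
#' squared arc length, globally rescaled so the rank-2 orientational
#' relaxation of the generator decays at `6 D`, the analytic isotropic-
#' diffusion rate.  The bound site exchanges with every surface site under
#' detailed balance with total exchange rate `k_ex = k_on + k_off`,
#' `k_on / k_off = p_bound / (1 - p_bound)`.
#'
#' @param d_coeff rotational diffusion coefficient, rad^2/s.
#' @param n_surface number of surface sites (>= 12; 192 at full scale).
#' @param cq_bound_hz `Cq` of the bound (rigid) site, Hz.
#' @param k_ex total free/bound exchange rate constant, 1/s.
#' @param p_bound bound-state population, in (0, 1).
#' @param cq_surface_hz `Cq` of the surface sites, Hz (defaults to
#'   `cq_bound_hz`: binding quenches the diffusion, not the local tensor).
#' @param n_neighbors neighbours per site in the diffusion graph.
#' @return an [exchange_network()] with `n_surface + 1` sites (bound last).
#' @export
sphere_diffusion_plus_bound <- function(d_coeff, n_surface = 192,
                                        cq_bound_hz = 55.3e3, k_ex = 0,
                                        p_bound = 0.08,
                                        cq_surface_hz = cq_bound_hz,
                                        n_neighbors = 6) {
  stopifnot(n_surface >= 12)
  if (p_bound <= 0 || p_bound >= 1) stop("`p_bound` must lie in (0, 1)")
  pts <- fibonacci_sphere(n_surface)
  K0 <- sphere_graph_generator(pts, n_neighbors)
  lam2 <- rank_l_relaxation_rate(K0, pts, l = 2)
  Ksurf <- K0 * (6 * d_coeff / lam2)

  n <- n_surface + 1
  K <- matrix(0, n, n)
  K[seq_len(n_surface), seq_len(n_surface)] <- Ksurf
  k_on <- k_ex * p_bound                 # each surface site -> bound
  k_off_each <- k_ex * (1 - p_bound) / n_surface  # bound -> each surface site
  K[n, seq_len(n_surface)] <- K[n, seq_len(n_surface)] + k_on
  K[seq_len(n_surface), n] <- k_off_each
  diag(K) <- 0
  diag(K) <- -colSums(K)

  p_surf <- (1 - p_bound) / n_surface
  sites <- lapply(seq_len(n_surface), function(i) {
    az <- atan2(pts[i, 2], pts[i, 1])
    pol <- acos(min(max(pts[i, 3], -1), 1))
    new_site(quad_tensor(cq_surface_hz, 0, c(az, pol, 0)), p_surf)
  })
  sites[[n]] <- new_site(quad_tensor(cq_bound_hz, 0, c(0, 0, 0)), p_bound)
  exchange_network(sites, K)
}

# near-uniform deterministic point set (golden-spiral lattice), n x 3
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

# symmetric nearest-neighbour generator with 1/arc^2 edge weights
sphere_graph_generator <- function(pts, n_neighbors) {
  n <- nrow(pts)
  G <- pts %*% t(pts)
  G[G > 1] <- 1; G[G < -1] <- -1
  arc <- acos(G)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(arc[i, ])[2:(n_neighbors + 1)]
    W[i, nb] <- 1 / arc[i, nb]^2
  }
  W <- pmax(W, t(W))                    # symmetrize (union of neighbourhoods)
  diag(W) <- 0
  diag(W) <- -colSums(W)
  W
}

# decay rate of the rank-l orientational correlation under generator K
# (uniform populations): Rayleigh quotient of -K over the rank-l harmonics.
rank_l_relaxation_rate <- function(K, pts, l = 2) {
  f <- real_harmonics(pts, l)
  num <- sum(vapply(seq_len(ncol(f)), function(m) {
    -sum(f[, m] * (K %*% f[, m]))
  }, numeric(1)))
  den <- sum(f^2)
  num / den
}

real_harmonics <- function(pts, l) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  if (l == 1) {
    cbind(x, y, z)
  } else if (l == 2) {
    cbind(x * y, x * z, y * z, x^2 - y^2, 3 * z^2 - 1)
  } else {
    stop("only l = 1, 2 supported")
  }
}

#' Direct product of two exchange processes
#'
#' Composes a slow outer motion (e.g. a rotameric flip of the methyl axis)
#' with a fast inner motion defined in the outer sites' local frames (e.g.
#' methyl three-site jumps about that axis).  The composite network has
#' `N_outer x N_inner` sites whose tensors are the inner tensors rotated by
#' the outer site orientations, populations multiply, and the kinetic
#' generator is `K_outer (x) I + I (x) K_inner` (the two processes are
#' independent).  Used to check that explicitly including fast methyl jumps
#' reproduces the pre-averaged-tensor description.
#'
#' @param outer,inner [exchange_network()]s; the inner tensors are expressed
#'   in each outer site's frame.
#' @return an [exchange_network()] with `N_outer * N_inner` sites.
#' @export
compose_exchange <- function(outer, inner) {
  n1 <- length(outer$sites); n2 <- length(inner$sites)
  sites <- vector("list", n1 * n2)
  for (i in seq_len(n1)) {
    R1 <- euler_rot(outer$sites[[i]]$tensor$euler)
    for (k in seq_len(n2)) {
      tin <- inner$sites[[k]]$tensor
      R <- R1 %*% euler_rot(tin$euler)
      sites[[(i - 1) * n2 + k]] <- new_site(
        quad_tensor(tin$cq_hz, tin$eta, euler_from_rot(R)),
        outer$sites[[i]]$population * inner$sites[[k]]$population)
    }
  }
  K <- kronecker(outer$rates, diag(n2)) + kronecker(diag(n1), inner$rates)
  exchange_network(sites, K)
}

#' Single-site (no-motion) network
#'
#' One site, no exchange: the coherent-only reference used for rotary
#' resonance positions and no-motion CEST profiles.
#'
#' @inheritParams quad_tensor
#' @return an [exchange_network()] with one site.
#' @export
single_site <- function(cq_hz, eta = 0, euler = c(0, 0, 0)) {
  exchange_network(list(new_site(quad_tensor(cq_hz, eta, euler), 1)),
                   matrix(0, 1, 1))
}

#' Build a named exchange model
#'
#' Dispatch used by configuration files: `name` is one of `"two_site_flip"`,
#' `"methyl_three_site"` or `"sphere_diffusion_plus_bound"`, and `args` the
#' keyword parameters of the corresponding builder.
#'
#' @param name builder name.
#' @param args named list of builder arguments.
#' @return an [exchange_network()].
#' @export
build_exchange_model <- function(name, args = list()) {
  builder <- switch(name,
    single_site = single_site,
    two_site_flip = two_site_flip,
    methyl_three_site = methyl_three_site,
    sphere_diffusion_plus_bound = sphere_diffusion_plus_bound,
    stop("unknown exchange model: ", name)
  )
  do.call(builder, args)
}
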