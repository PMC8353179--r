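#' Powder orientation sets
#'
#' Deterministic (seedless) sets of crystallite orientations `(alpha, beta)`
#' with weights summing to 1.  Schemes: `"spiral"` - generalized spiral
#' (uniform in `cos beta`, azimuth advanced by arc length; equal weights);
#' `"golden"` - golden-angle (Fibonacci) lattice, equal weights;
#' `"grid"` - product grid in `(beta, alpha)` with `sin(beta)` weights
#' (the returned size is the nearest product grid to `n`).
#'
#' @param n requested number of orientations (>= 1).
#' @param scheme orientation scheme.
#' @return tibble of class `powder_set` with columns `alpha`, `beta`, `weight`.
#' @export
powder_orientations <- function(n, scheme = c("spiral", "golden", "grid")) {
  scheme <- match.arg(scheme)
  stopifnot(n >= 1)
  out <- switch(scheme,
    spiral = {
      if (n == 1) {
        tibble::tibble(alpha = 0, beta = magic_angle(), weight = 1)
      } else {
        z <- seq(-1, 1, length.out = n)
        beta <- acos(z)
        alpha <- numeric(n)
        for (i in 2:n) {
          s <- 1 - z[i]^2
          alpha[i] <- if (s < 1e-12) 0 else
            (alpha[i - 1] + 3.6 / sqrt(n * s)) %% (2 * pi)
        }
        tibble::tibble(alpha = alpha, beta = beta, weight = rep(1 / n, n))
      }
    },
    golden = {
      i <- seq_len(n) - 0.5
      z <- 1 - 2 * i / n
      tibble::tibble(alpha = (pi * (1 + sqrt(5)) * i) %% (2 * pi),
                     beta = acos(z), weight = rep(1 / n, n))
    },
    grid = {
      nb <- max(2L, round(sqrt(n / 2)))
      na <- max(1L, ceiling(n / nb))
      beta <- (seq_len(nb) - 0.5) * pi / nb
      alpha <- (seq_len(na) - 1) * 2 * pi / na
      g <- expand.grid(alpha = alpha, beta = beta)
      w <- sin(g$beta)
      tibble::tibble(alpha = g$alpha, beta = g$beta, weight = w / sum(w))
    }
  )
  class(out) <- c("powder_set", class(out))
  out
}

# iterate a powder set as crystallite objects
as_crystallites <- function(powder) {
  lapply(seq_len(nrow(powder)), function(i) {
    crystallite(powder$alpha[i], powder$beta[i], powder$weight[i])
  })
}
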