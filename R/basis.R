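#' Spin-1 coherence basis
#'
#' Returns the eight traceless Hermitian 3x3 matrices that, together with the
#' identity, span the spin-1 density matrix: the four single-quantum operators
#' `Sx`, `Sy`, `Jx`, `Jy`, the two double-quantum operators `Jz` and `K`,
#' Zeeman order `Sz` and quadrupolar order `Q`.  Normalization is fixed by
#' trace-orthonormality, `Tr(O_i O_j) = delta_ij`, which makes the expansion
#' coefficients of a density matrix an orthonormal coordinate vector and the
#' commutator superoperator of any Hermitian Hamiltonian a real antisymmetric
#' matrix in this basis.
#'
#' @return Named list of eight complex 3x3 matrices, in the order
#'   `Sx, Sy, Jx, Jy, Jz, K, Sz, Q`.
#' @examples
#' b <- spin_basis()
#' Re(sum(diag(b$Q %*% b$Q)))  # 1
#' @export
spin_basis <- function() {
  if (!is.null(.qcest_cache$basis)) return(.qcest_cache$basis)
  i <- 1i
  m <- function(...) matrix(c(...), 3, 3, byrow = TRUE)
  b <- list(
    Sx = m(0, 1, 0,  1, 0, 1,  0, 1, 0) / 2,
    Sy = m(0, -i, 0,  i, 0, -i,  0, i, 0) / 2,
    Jx = m(0, -i, 0,  i, 0, i,  0, -i, 0) / 2,
    Jy = m(0, 1, 0,  1, 0, -1,  0, -1, 0) / 2,
    Jz = m(0, 0, -i,  0, 0, 0,  i, 0, 0) / sqrt(2),
    K  = m(0, 0, 1,  0, 0, 0,  1, 0, 0) / sqrt(2),
    Sz = m(1, 0, 0,  0, 0, 0,  0, 0, -1) / sqrt(2),
    Q  = m(1, 0, 0,  0, -2, 0,  0, 0, 1) / sqrt(6)
  )
  .qcest_cache$basis <- b
  b
}

#' Conventional spin-1 angular momentum operators
#'
#' The textbook operators with `[Ix, Iy] = i Iz`, used as an independent
#' construction route for Hamiltonians and relaxation spin factors.
#'
#' @return Named list with `Ix`, `Iy`, `Iz` (complex 3x3) and the identity `E`.
#' @export
spin1_operators <- function() {
  i <- 1i
  s2 <- 1 / sqrt(2)
  list(
    Ix = matrix(c(0, s2, 0, s2, 0, s2, 0, s2, 0), 3, 3, byrow = TRUE),
    Iy = matrix(c(0, -i * s2, 0, i * s2, 0, -i * s2, 0, i * s2, 0), 3, 3, byrow = TRUE),
    Iz = diag(c(1, 0, -1)) + 0i,
    E  = diag(3) + 0i
  )
}

# order of the coherence labels everywhere in the package
coherence_names <- function() c("Sx", "Sy", "Jx", "Jy", "Jz", "K", "Sz", "Q")

#' Commutator superoperator in the coherence basis
#'
#' For a Hermitian 3x3 Hamiltonian `H` (rad/s), returns the 8x8 real matrix
#' `M` with `M[a, b] = Re(-i Tr(O_a [H, O_b]))`, so that coefficient vectors
#' `c` of the density matrix evolve as `dc/dt = M c`.  `M` is antisymmetric,
#' hence coherent evolution is norm-preserving.
#'
#' @param H complex Hermitian 3x3 matrix, angular frequency units.
#' @return 8x8 real matrix.
#' @export
comm_superop <- function(H) {
  b <- spin_basis()
  M <- matrix(0, 8, 8)
  for (bb in 1:8) {
    C <- H %*% b[[bb]] - b[[bb]] %*% H
    for (aa in 1:8) {
      M[aa, bb] <- Re(-1i * sum(diag(Conj(t(b[[aa]])) %*% C)))
    }
  }
  M
}

# Superoperator generators for the three Hamiltonian channels: unit
# quadrupolar frequency, unit RF field and unit offset (all rad/s).  The
# tilted-frame Hamiltonian is H = sqrt(2/3) wQ Q + sqrt(2) wRF Sx + sqrt(2) W Sz,
# so its superoperator is wQ * SQ + wRF * SX + W * SZ.
hamiltonian_superops <- function() {
  if (!is.null(.qcest_cache$superops)) return(.qcest_cache$superops)
  b <- spin_basis()
  so <- list(
    SQ = comm_superop(sqrt(2 / 3) * b$Q),
    SX = comm_superop(sqrt(2) * b$Sx),
    SZ = comm_superop(sqrt(2) * b$Sz)
  )
  .qcest_cache$superops <- so
  so
}

.qcest_cache <- new.env(parent = emptyenv())
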