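// Dense real matrix exponentials and time-ordered rotor-period products.
// All Liouvillians handled here are real: the commutator superoperator of a
// Hermitian Hamiltonian on a trace-orthonormal Hermitian basis is real
// antisymmetric, and exchange/relaxation terms are real.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& L) {
  return expmat(L);
}

// Time-ordered product of per-step exponentials: slice 0 acts first,
// U = expm(L[n-1] dt) ... expm(L[1] dt) expm(L[0] dt).
// [[Rcpp::export]]
arma::mat cpp_step_prod(const arma::cube& L, const double dt) {
  const uword n = L.n_slices;
  mat U = expmat(L.slice(0) * dt);
  for (uword j = 1; j < n; ++j) {
    U = expmat(L.slice(j) * dt) * U;
  }
  return U;
}

// Exponentials of each slice (for detection substeps), slice j -> expm(L_j dt_j).
// [[Rcpp::export]]
arma::cube cpp_step_expm(const arma::cube& L, const arma::vec& dt) {
  cube E(size(L));
  for (uword j = 0; j < L.n_slices; ++j) {
    E.slice(j) = expmat(L.slice(j) * dt(j));
  }
  return E;
}

// Binary matrix power, m >= 0.
// [[Rcpp::export]]
arma::mat cpp_mat_pow(const arma::mat& U, const int m) {
  mat P = eye(U.n_rows, U.n_cols);
  if (m <= 0) return P;
  mat B = U;
  int k = m;
  while (k > 0) {
    if (k & 1) P = B * P;
    B = B * B;
    k >>= 1;
  }
  return P;
}

// Repeated application of a cycle of substep propagators to a state vector,
// recording the state after each full cycle. E: n x n x s cube, slice 0 first.
// Returns n x (n_cycles + 1) matrix whose column k is the state after k cycles.
// [[Rcpp::export]]
arma::mat cpp_cycle_states(const arma::cube& E, const arma::vec& v0,
                           const int n_cycles) {
  const uword n = v0.n_elem;
  mat out(n, n_cycles + 1);
  vec v = v0;
  out.col(0) = v;
  for (int k = 0; k < n_cycles; ++k) {
    for (uword j = 0; j < E.n_slices; ++j) v = E.slice(j) * v;
    out.col(k + 1) = v;
  }
  return out;
}

// FID sampling: starting state v0, apply substep propagators cyclically
// (slice order 0..s-1, repeating), recording the observable re + i*im
// (given as index vectors, 0-based) every `per` substeps, n_points times.
// [[Rcpp::export]]
arma::cx_vec cpp_sample_fid(const arma::cube& E, const arma::vec& v0,
                            const arma::uvec& idx_re, const arma::uvec& idx_im,
                            const int per, const int n_points) {
  cx_vec fid(n_points);
  vec v = v0;
  uword slice = 0;
  const uword s = E.n_slices;
  fid(0) = cx_double(accu(v.elem(idx_re)), accu(v.elem(idx_im)));
  for (int k = 1; k < n_points; ++k) {
    for (int j = 0; j < per; ++j) {
      v = E.slice(slice) * v;
      slice = (slice + 1) % s;
    }
    fid(k) = cx_double(accu(v.elem(idx_re)), accu(v.elem(idx_im)));
  }
  return fid;
}
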