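// Fixed-point EM engine for Lp-penalized least squares (p in [0,2]).
//
// Iterates theta <- (D X'X + lambda I)^-1 D X'y with D = diag(|eta|^(2-p)),
// eta <- theta, restricted to the active (nonzero) support.  The solve is
// carried out either on the k x k active Gram system or on the equivalent
// n x n dual system theta = D X'(X D X' + lambda I)^-1 y, whichever is
// smaller (or as forced by `mode`).  Exact zeros are absorbing: once a
// coefficient is pruned below zero_eps it never re-enters the support.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Symmetrized active solve: with s_j = |eta_j|^((2-p)/2) and theta = s % u,
// (diag(s) G diag(s) + lambda I) u = s % z  is SPD and equivalent to the
// nonsymmetric M-step system.
static vec active_step_primal(const mat& Gaa, const vec& za, const vec& s,
                              double lambda) {
  mat M = Gaa;
  M.each_col() %= s;
  M.each_row() %= s.t();
  M.diag() += lambda;
  vec u = solve(M, s % za, solve_opts::likely_sympd);
  return s % u;
}

static vec active_step_dual(const mat& Xa, const vec& y, const vec& s,
                            double lambda) {
  mat U = Xa;
  U.each_row() %= s.t();              // U = X_A diag(s)
  mat M = U * U.t();                  // X_A D X_A'
  M.diag() += lambda;
  vec w = solve(M, y, solve_opts::likely_sympd);
  return s % (U.t() * w);
}

// mode: 0 = auto (primal when k <= n), 1 = primal always, 2 = dual always.
// G/z may be empty (0 x 0 / length 0); then Gram blocks are formed from X.
// [[Rcpp::export(name = ".em_engine_cpp")]]
Rcpp::List em_engine(const arma::mat& X, const arma::vec& y, double lambda,
                     double p, double tol, int max_iter, double zero_eps,
                     const arma::vec& theta0, bool positive_only, int mode,
                     const arma::mat& G, const arma::vec& z) {
  const uword n = X.n_rows, m = X.n_cols;
  const bool has_G = (G.n_rows == m && G.n_cols == m);
  const bool has_z = (z.n_elem == m);

  vec theta = theta0;
  if (positive_only) theta.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  uvec active = find(abs(theta) > 0.0);
  // below-threshold entries of the init are pruned up front
  if (zero_eps > 0.0) {
    for (uword idx : active) if (std::abs(theta(idx)) < zero_eps) theta(idx) = 0.0;
    active = find(abs(theta) != 0.0);
  }

  bool converged = active.n_elem == 0;   // theta = 0 is an exact fixed point
  int iter = 0;
  vec za_full;
  if (!has_z && active.n_elem > 0) za_full = X.t() * y;

  while (iter < max_iter && !converged) {
    ++iter;
    const uword k = active.n_elem;
    vec eta = theta.elem(active);
    vec s = pow(abs(eta), (2.0 - p) / 2.0);

    bool primal = (mode == 1) || (mode == 0 && k <= n);
    vec th_new;
    if (primal) {
      mat Gaa;
      vec za;
      if (has_G) Gaa = G.submat(active, active);
      else { mat Xa = X.cols(active); Gaa = Xa.t() * Xa; }
      za = has_z ? vec(z.elem(active)) : vec(za_full.elem(active));
      th_new = active_step_primal(Gaa, za, s, lambda);
    } else {
      th_new = active_step_dual(X.cols(active), y, s, lambda);
    }

    if (positive_only) th_new.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    for (uword i = 0; i < k; ++i)
      if (std::abs(th_new(i)) < zero_eps) th_new(i) = 0.0;

    double delta = 0.0;
    for (uword i = 0; i < k; ++i)
      delta = std::max(delta, std::abs(th_new(i) - eta(i)));

    for (uword i = 0; i < k; ++i) theta(active(i)) = th_new(i);
    active = active.elem(find(th_new != 0.0));

    if (delta < tol || active.n_elem == 0) { converged = true; break; }
  }

  return Rcpp::List::create(Rcpp::Named("theta") = theta,
                            Rcpp::Named("n_iter") = iter,
                            Rcpp::Named("converged") = converged);
}
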