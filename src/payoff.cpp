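// Fast payoff kernel for ergodic strategy pairs.  Builds the 4x4 round
// chain (alternating or simultaneous), applies the error transform, and
// solves for the stationary distribution.  Returns NA when the chain does
// not have a unique stationary distribution (degenerate deterministic
// pairs); the R code then falls back to the communicating-class
// decomposition.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".pay_kernel")]]
Rcpp::NumericVector pay_kernel(Rcpp::NumericVector p_, Rcpp::NumericVector q_,
                               bool alternating, double b, double c,
                               double eps) {
  vec p(4), q(4);
  for (int i = 0; i < 4; ++i) { p[i] = p_[i]; q[i] = q_[i]; }
  if (eps > 0) {
    p = (1 - eps) * p + eps * (1 - p);
    q = (1 - eps) * q + eps * (1 - q);
  }
  mat M(4, 4);
  if (alternating) {
    // from (i, j): player 1 acts on (i, j), player 2 responds to (j, i')
    double qr[4] = {q[0], q[2], q[0], q[2]};  // q_{j, C} per row
    double qs[4] = {q[1], q[3], q[1], q[3]};  // q_{j, D} per row
    for (int r = 0; r < 4; ++r) {
      M(r, 0) = p[r] * qr[r];
      M(r, 1) = p[r] * (1 - qr[r]);
      M(r, 2) = (1 - p[r]) * qs[r];
      M(r, 3) = (1 - p[r]) * (1 - qs[r]);
    }
  } else {
    double qq[4] = {q[0], q[2], q[1], q[3]};  // q_{j, i} per state order
    for (int r = 0; r < 4; ++r) {
      M(r, 0) = p[r] * qq[r];
      M(r, 1) = p[r] * (1 - qq[r]);
      M(r, 2) = (1 - p[r]) * qq[r];
      M(r, 3) = (1 - p[r]) * (1 - qq[r]);
    }
  }
  mat A = M.t() - eye(4, 4);
  A.row(3).ones();
  vec rhs = {0, 0, 0, 1};
  vec v;
  bool ok = solve(v, A, rhs, solve_opts::no_approx + solve_opts::fast);
  if (!ok)
    return Rcpp::NumericVector::create(NA_REAL);
  vec resid = M.t() * v - v;
  if (v.min() < -1e-9 || abs(resid).max() > 1e-8)
    return Rcpp::NumericVector::create(NA_REAL);
  v = clamp(v, 0.0, datum::inf);
  v /= accu(v);
  double rho1 = v[0] + v[1], rho2 = v[0] + v[2];
  return Rcpp::NumericVector::create(rho2 * b - rho1 * c,
                                     rho1 * b - rho2 * c, rho1, rho2);
}
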