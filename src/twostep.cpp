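// Compiled hot paths: the trial-sequence log-likelihood evaluated inside
// the optimizer, and the multi-response Huber IRLS used for the
// mass-univariate single-trial EEG regression.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// par = (alpha, lam, beta, w, pi, rho); s2c = 1 if second stage is C.
// Mirrors the R reference in sequence_loglik() exactly.
// [[Rcpp::export]]
double cpp_sequence_loglik(NumericVector par, IntegerVector a1,
                           IntegerVector s2c, IntegerVector a2,
                           NumericVector reward, IntegerVector valid,
                           double p_common) {
  const double alpha = par[0], lam = par[1], beta = par[2], w = par[3],
               cpi = par[4], rho = par[5];
  double q[3][2] = {{0, 0}, {0, 0}, {0, 0}};
  const int n = a1.size();
  int prev = -1;  // previous stage-1 action, -1 = none
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    if (!valid[t]) { prev = -1; continue; }
    const int c1 = a1[t], s2i = s2c[t] ? 2 : 1, c2 = a2[t];
    const double mB = std::max(q[1][0], q[1][1]);
    const double mC = std::max(q[2][0], q[2][1]);
    const double qmb0 = p_common * mB + (1 - p_common) * mC;
    const double qmb1 = (1 - p_common) * mB + p_common * mC;
    double v0 = w * qmb0 + (1 - w) * q[0][0];
    double v1 = w * qmb1 + (1 - w) * q[0][1];
    if (prev == 0) v0 += cpi + rho; else if (prev == 1) v1 += cpi + rho;
    v0 *= beta; v1 *= beta;
    const double m1 = std::max(v0, v1);
    const double lse1 = m1 + std::log(std::exp(v0 - m1) + std::exp(v1 - m1));
    ll += (c1 == 0 ? v0 : v1) - lse1;
    const double u0 = beta * q[s2i][0], u1 = beta * q[s2i][1];
    const double m2 = std::max(u0, u1);
    const double lse2 = m2 + std::log(std::exp(u0 - m2) + std::exp(u1 - m2));
    ll += (c2 == 0 ? u0 : u1) - lse2;
    const double d1 = q[s2i][c2] - q[0][c1];
    const double d2 = reward[t] - q[s2i][c2];
    q[0][c1] += alpha * d1 + alpha * lam * d2;
    q[s2i][c2] += alpha * d2;
    prev = c1;
  }
  return ll;
}

// Huber IRLS for a shared design X (n x p) against many responses
// Y (n x m): one robust fit per column, each with its own MAD scale and
// weights. Returns the p x m coefficient matrix. k is the Huber tuning
// constant; k = Inf reduces every fit to OLS.
// [[Rcpp::export]]
arma::mat cpp_huber_irls(const arma::mat& X, const arma::mat& Y, double k,
                         int max_iter, double tol) {
  const arma::uword p = X.n_cols, m = Y.n_cols;
  arma::mat XtX = X.t() * X;
  arma::mat B = arma::solve(XtX, X.t() * Y, arma::solve_opts::likely_sympd);
  if (!std::isfinite(k)) return B;
  for (arma::uword j = 0; j < m; ++j) {
    arma::vec y = Y.col(j);
    arma::vec b = B.col(j);
    for (int it = 0; it < max_iter; ++it) {
      arma::vec r = y - X * b;
      double s = 1.4826 * arma::median(arma::abs(r));
      if (s < 1e-12) break;  // (near-)exact fit: weights all saturate
      arma::vec wgt = arma::clamp(k * s / arma::abs(r), 0.0, 1.0);
      arma::mat Xw = X.each_col() % wgt;
      arma::vec bn = arma::solve(X.t() * Xw, Xw.t() * y,
                                 arma::solve_opts::likely_sympd);
      double change = arma::max(arma::abs(bn - b));
      b = bn;
      if (change < tol * (1.0 + arma::max(arma::abs(b)))) break;
    }
    B.col(j) = b;
  }
  return B;
}
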