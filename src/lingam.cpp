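// Pairwise exogeneity scoring for DirectLiNGAM order search.
// The O(m^2) pair sweep with per-pair residual entropies is the hot loop
// of the causal-order search; everything else stays in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Differential entropy of a standardized sample via the maximum-entropy
// approximation (log cosh and u*exp(-u^2/2) contrasts).
static double entropy_std(const vec& u) {
  const double k1 = 79.047, k2 = 7.4129, gam = 0.37457;
  const double m1 = mean(log(cosh(u)));
  const double m2 = mean(u % exp(-0.5 * square(u)));
  return 0.5 * (1.0 + std::log(2.0 * M_PI))
       - k1 * (m1 - gam) * (m1 - gam) - k2 * m2 * m2;
}

// X: samples x m with centered columns.  Returns, per variable i, the sum
// of squared negative parts of the mutual-information differences against
// every other variable; the most exogenous variable minimizes this.
// [[Rcpp::export]]
arma::vec lingam_exogeneity_scores(const arma::mat& X) {
  const uword m = X.n_cols;
  const mat C = cov(X);
  const vec sds = sqrt(C.diag());
  vec hx(m);
  for (uword i = 0; i < m; ++i) {
    hx(i) = sds(i) > 0 ? entropy_std(X.col(i) / sds(i)) : 0.0;
  }
  mat eres(m, m, fill::zeros);
  for (uword j = 0; j < m; ++j) {
    if (C(j, j) <= 0) continue;
    const vec b = C.col(j) / C(j, j);
    for (uword i = 0; i < m; ++i) {
      if (i == j) continue;
      const vec r = X.col(i) - b(i) * X.col(j);
      const double s = stddev(r);
      eres(i, j) = s > 0 ? entropy_std(r / s) : 0.0;
    }
  }
  vec score(m, fill::zeros);
  for (uword i = 0; i < m; ++i) {
    double acc = 0.0;
    for (uword j = 0; j < m; ++j) {
      if (i == j) continue;
      const double d = hx(j) - hx(i) + eres(i, j) - eres(j, i);
      if (d < 0) acc += d * d;
    }
    score(i) = acc;
  }
  return score;
}
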