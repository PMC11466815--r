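// Fast minimal-IMAP construction for the Fisher-z partial-correlation tester.
// For a variable ordering pi, the minimal IMAP has an arc pi[a] -> pi[b]
// (a < b) exactly when pi[a] and pi[b] are dependent given the remaining
// prefix {pi[1], ..., pi[b-1]} \ {pi[a]}. All such partial correlations for a
// fixed b come from one inversion of the leading b x b submatrix of the
// permuted correlation matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".imap_perm_fisher_z")]]
LogicalMatrix imap_perm_fisher_z(const arma::mat& C, const int n,
                                 const double alpha,
                                 const IntegerVector& perm) {
  const int p = perm.size();
  LogicalMatrix adj(p, p);
  arma::uvec idx(p);
  for (int k = 0; k < p; ++k) idx[k] = perm[k] - 1;

  for (int b = 1; b < p; ++b) {
    arma::uvec pre = idx.head(b + 1);
    arma::mat sub = C.submat(pre, pre);
    arma::mat theta;
    if (!arma::inv_sympd(theta, sub)) {
      theta = arma::inv(sub + 1e-8 * arma::eye(b + 1, b + 1));
    }
    const double df = n - (b - 1) - 3;
    for (int a = 0; a < b; ++a) {
      double r = -theta(a, b) / std::sqrt(theta(a, a) * theta(b, b));
      if (r > 1.0 - 1e-12) r = 1.0 - 1e-12;
      if (r < -1.0 + 1e-12) r = -1.0 + 1e-12;
      const double z = std::atanh(r);
      const double stat = std::sqrt(df > 1.0 ? df : 1.0) * std::fabs(z);
      const double pval = 2.0 * R::pnorm(-stat, 0.0, 1.0, 1, 0);
      if (pval < alpha) adj(idx[a], idx[b]) = true;
    }
  }
  return adj;
}
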