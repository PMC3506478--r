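// Felsenstein pruning kernel.  The tree arrives as a postorder edge
// list; tip data as per-tip partial-likelihood matrices plus an integer
// state index per site (0 = ambiguous/gap, forcing the dense path).
// Transition matrices come from the symmetrized eigendecomposition of
// the reversible rate matrix: P(t) = U diag(exp(lambda t)) Uinv.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector prune_loglik_cpp(IntegerMatrix edge, NumericVector el,
                               int ntip, int nnode, List tip_parts,
                               IntegerMatrix tip_idx, NumericMatrix U,
                               NumericMatrix Uinv, NumericVector eval,
                               NumericVector freq, double rate) {
  const int ns = U.nrow();
  const int nedge = edge.nrow();
  const int S = tip_idx.ncol();
  arma::mat Um(U.begin(), ns, ns, false);
  arma::mat Uim(Uinv.begin(), ns, ns, false);
  arma::vec ev(eval.begin(), ns, false);
  arma::vec fq(freq.begin(), ns, false);

  std::vector<arma::mat> parts(nnode);
  std::vector<bool> has(nnode, false);
  arma::rowvec logscale(S, arma::fill::zeros);

  for (int k = 0; k < nedge; ++k) {
    int par = edge(k, 0) - 1, ch = edge(k, 1) - 1;
    double t = rate * el[k];
    if (!std::isfinite(t) || t < 0)
      stop("non-finite or negative branch length");
    arma::vec e = arma::exp(ev * t);
    arma::mat P = Um * (Uim.each_col() % e);
    P.transform([](double x) { return x < 0 ? 0.0 : x; });

    arma::mat contrib(ns, S);
    if (ch < ntip) {
      NumericMatrix tp = tip_parts[ch];
      arma::mat tpm(tp.begin(), ns, S, false);
      for (int s = 0; s < S; ++s) {
        int idx = tip_idx(ch, s);
        if (idx > 0) {
          contrib.col(s) = P.col(idx - 1);
        } else {
          contrib.col(s) = P * tpm.col(s);
        }
      }
    } else {
      contrib = P * parts[ch];
    }
    if (!has[par]) {
      parts[par] = contrib;
      has[par] = true;
    } else {
      parts[par] %= contrib;
      arma::rowvec mx = arma::max(parts[par], 0);
      mx.transform([](double x) { return x <= 0 ? 1.0 : x; });
      logscale += arma::log(mx);
      parts[par].each_row() /= mx;
    }
  }
  int root = edge(nedge - 1, 0) - 1;
  arma::rowvec lik = fq.t() * parts[root];
  NumericVector out(S);
  for (int s = 0; s < S; ++s) out[s] = std::log(lik(s)) + logscale(s);
  return out;
}
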