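// Pruning log-likelihood of the GY94/M0 model on the fixed unrooted
// quartet ((focal, sister), out1, out2). Transition matrices come from
// the symmetrized eigendecomposition of the reversible generator, shared
// across the five branches within one evaluation.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// patterns: n_pat x 4 matrix of 0-based codon-state indices
//           (columns: focal, sister, out1, out2)
// weights:  pattern multiplicities
// Q:        61x61 generator (rows sum to zero), pi-reversible
// pi:       stationary codon distribution
// t:        branch lengths (focal, sister, out1, out2, internal)
// [[Rcpp::export]]
double quartet_loglik_cpp(const arma::umat& patterns,
                          const arma::vec& weights,
                          const arma::mat& Q,
                          const arma::vec& pi,
                          const arma::vec& t) {
  const arma::uword n = Q.n_rows;
  arma::vec sq = arma::sqrt(pi);
  arma::mat B = Q;
  B.each_col() %= sq;       // D^{1/2} Q
  B.each_row() /= sq.t();   // ... D^{-1/2}
  B = (B + B.t()) / 2.0;

  arma::vec eval;
  arma::mat evec;
  if (!arma::eig_sym(eval, evec, B, "dc")) return -arma::datum::inf;

  std::vector<arma::mat> P(5);
  for (int k = 0; k < 5; ++k) {
    arma::mat E = evec * arma::diagmat(arma::exp(eval * t[k])) * evec.t();
    E.each_col() /= sq;     // D^{-1/2} E
    E.each_row() %= sq.t(); // ... D^{1/2}
    E.elem(arma::find(E < 0.0)).zeros();  // eigen round-off
    P[k] = E;
  }

  arma::mat inner = P[2].cols(patterns.col(2)) % P[3].cols(patterns.col(3));
  arma::mat up = P[4] * inner;
  arma::mat L = P[0].cols(patterns.col(0)) % P[1].cols(patterns.col(1)) % up;
  L.each_col() %= pi;
  arma::rowvec site = arma::sum(L, 0);
  if (site.min() <= 0.0 || !site.is_finite()) return -arma::datum::inf;
  return arma::dot(weights, arma::log(site.t()));
}
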