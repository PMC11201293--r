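#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Log-domain forward-backward and Viterbi for one observation sequence given
// per-frame state log-densities. Sequence boundaries are respected by calling
// these once per subject; sufficient statistics are accumulated by the caller.

static double logsumexp(const arma::rowvec& v) {
  double m = v.max();
  if (!arma::is_finite(m)) return m;
  return m + std::log(arma::accu(arma::exp(v - m)));
}

// [[Rcpp::export]]
List hmm_estep_cpp(const arma::mat& logB, const arma::vec& logpi,
                   const arma::mat& logA) {
  const int T = logB.n_rows, K = logB.n_cols;
  arma::mat la(T, K), lb(T, K, arma::fill::zeros);
  la.row(0) = logpi.t() + logB.row(0);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k)
      la(t, k) = logsumexp(la.row(t - 1) + logA.col(k).t()) + logB(t, k);
  const double ll = logsumexp(la.row(T - 1));
  for (int t = T - 2; t >= 0; --t)
    for (int k = 0; k < K; ++k)
      lb(t, k) = logsumexp(logA.row(k) + logB.row(t + 1) + lb.row(t + 1));
  arma::mat gamma = la + lb - ll;
  gamma = arma::exp(gamma);
  gamma.each_col() /= arma::sum(gamma, 1);  // guard drift
  // xi summed over t: expected transition counts
  arma::mat xi(K, K, arma::fill::zeros);
  for (int t = 0; t + 1 < T; ++t) {
    arma::mat m(K, K);
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        m(i, j) = la(t, i) + logA(i, j) + logB(t + 1, j) + lb(t + 1, j) - ll;
    xi += arma::exp(m);
  }
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(const arma::mat& logB, const arma::vec& logpi,
                              const arma::mat& logA) {
  const int T = logB.n_rows, K = logB.n_cols;
  arma::mat delta(T, K);
  arma::imat psi(T, K, arma::fill::zeros);
  delta.row(0) = logpi.t() + logB.row(0);
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      arma::rowvec cand = delta.row(t - 1) + logA.col(k).t();
      arma::uword best;
      double v = cand.max(best);
      delta(t, k) = v + logB(t, k);
      psi(t, k) = best;
    }
  IntegerVector path(T);
  arma::uword best;
  delta.row(T - 1).max(best);
  path[T - 1] = best + 1;
  for (int t = T - 2; t >= 0; --t) {
    best = psi(t + 1, best);
    path[t] = best + 1;
  }
  return path;
}
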