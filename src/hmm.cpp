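#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a discrete-time HMM.
// B: T x K matrix of per-position emission likelihoods P(x_t | state k).
// trans: K x K transition matrix (rows sum to 1). init: length-K start
// distribution. Returns the log-likelihood, posterior state probabilities
// gamma (T x K) and the summed transition posteriors xi (K x K), which is
// all the Baum-Welch M-step needs.
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix B, NumericMatrix trans,
                          NumericVector init) {
  const int T = B.nrow(), K = B.ncol();
  if (trans.nrow() != K || trans.ncol() != K || init.size() != K)
    stop("dimension mismatch between emissions, transitions and init");
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), xisum(K, K);
  NumericVector cvec(T);

  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * B(0, k); s += alpha(0, k); }
  if (s <= 0.0) return List::create(_["loglik"] = R_NegInf);
  cvec[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;

  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int j = 0; j < K; ++j) acc += alpha(t - 1, j) * trans(j, k);
      acc *= B(t, k);
      alpha(t, k) = acc;
      s += acc;
    }
    if (s <= 0.0) return List::create(_["loglik"] = R_NegInf);
    cvec[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    const double cnext = cvec[t + 1];
    for (int j = 0; j < K; ++j) {
      double acc = 0.0;
      for (int k = 0; k < K; ++k) acc += trans(j, k) * B(t + 1, k) * beta(t + 1, k);
      beta(t, j) = acc / cnext;
    }
  }

  for (int t = 0; t < T; ++t) {
    double norm = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); norm += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= norm;
  }

  for (int t = 0; t < T - 1; ++t) {
    const double cnext = cvec[t + 1];
    for (int j = 0; j < K; ++j) {
      const double aj = alpha(t, j);
      for (int k = 0; k < K; ++k)
        xisum(j, k) += aj * trans(j, k) * B(t + 1, k) * beta(t + 1, k) / cnext;
    }
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(cvec[t]);
  return List::create(_["loglik"] = ll, _["gamma"] = gamma,
                      _["xisum"] = xisum);
}
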