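#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a discrete-emission HMM over a list of
// observation sequences (0-based microstate labels). Returns the total
// log-likelihood and the expected-count accumulators of one EM E-step:
// transition counts xi (m x m), emission counts gobs (m x n_obs) and
// initial-state counts g0 (m).
// [[Rcpp::export]]
List hmm_estep(List obs_list, NumericMatrix T, NumericMatrix B,
               NumericVector pi0) {
  const int m = T.nrow();
  const int n_obs = B.ncol();
  NumericMatrix xi(m, m), gobs(m, n_obs);
  NumericVector g0(m);
  double loglik = 0.0;

  for (int s = 0; s < obs_list.size(); ++s) {
    IntegerVector o = obs_list[s];
    const int L = o.size();
    if (L < 1) continue;
    NumericMatrix alpha(L, m), beta(L, m);
    NumericVector c(L);

    // forward with scaling
    double csum = 0.0;
    for (int i = 0; i < m; ++i) {
      alpha(0, i) = pi0[i] * B(i, o[0]);
      csum += alpha(0, i);
    }
    if (csum <= 0) stop("non-finite likelihood: zero-probability frame");
    c[0] = csum;
    for (int i = 0; i < m; ++i) alpha(0, i) /= csum;
    for (int t = 1; t < L; ++t) {
      csum = 0.0;
      for (int j = 0; j < m; ++j) {
        double a = 0.0;
        for (int i = 0; i < m; ++i) a += alpha(t - 1, i) * T(i, j);
        a *= B(j, o[t]);
        alpha(t, j) = a;
        csum += a;
      }
      if (csum <= 0) stop("non-finite likelihood: zero-probability frame");
      c[t] = csum;
      for (int j = 0; j < m; ++j) alpha(t, j) /= csum;
    }
    for (int t = 0; t < L; ++t) loglik += std::log(c[t]);

    // backward with the same scaling
    for (int i = 0; i < m; ++i) beta(L - 1, i) = 1.0;
    for (int t = L - 2; t >= 0; --t) {
      for (int i = 0; i < m; ++i) {
        double b = 0.0;
        for (int j = 0; j < m; ++j)
          b += T(i, j) * B(j, o[t + 1]) * beta(t + 1, j);
        beta(t, i) = b / c[t + 1];
      }
    }

    // accumulate expected counts
    for (int t = 0; t < L; ++t) {
      for (int i = 0; i < m; ++i) {
        double g = alpha(t, i) * beta(t, i);
        gobs(i, o[t]) += g;
        if (t == 0) g0[i] += g;
      }
    }
    for (int t = 0; t < L - 1; ++t) {
      for (int i = 0; i < m; ++i) {
        if (alpha(t, i) == 0.0) continue;
        for (int j = 0; j < m; ++j) {
          xi(i, j) += alpha(t, i) * T(i, j) * B(j, o[t + 1]) *
                      beta(t + 1, j) / c[t + 1];
        }
      }
    }
  }
  return List::create(_["loglik"] = loglik, _["xi"] = xi,
                      _["gobs"] = gobs, _["g0"] = g0);
}

// Posterior state probabilities (gamma) for one observation sequence.
// [[Rcpp::export]]
NumericMatrix hmm_posterior(IntegerVector o, NumericMatrix T,
                            NumericMatrix B, NumericVector pi0) {
  const int m = T.nrow();
  const int L = o.size();
  NumericMatrix alpha(L, m), beta(L, m), gamma(L, m);
  NumericVector c(L);
  double csum = 0.0;
  for (int i = 0; i < m; ++i) {
    alpha(0, i) = pi0[i] * B(i, o[0]);
    csum += alpha(0, i);
  }
  if (csum <= 0) stop("zero-probability frame");
  c[0] = csum;
  for (int i = 0; i < m; ++i) alpha(0, i) /= csum;
  for (int t = 1; t < L; ++t) {
    csum = 0.0;
    for (int j = 0; j < m; ++j) {
      double a = 0.0;
      for (int i = 0; i < m; ++i) a += alpha(t - 1, i) * T(i, j);
      a *= B(j, o[t]);
      alpha(t, j) = a;
      csum += a;
    }
    if (csum <= 0) stop("zero-probability frame");
    c[t] = csum;
    for (int j = 0; j < m; ++j) alpha(t, j) /= csum;
  }
  for (int i = 0; i < m; ++i) beta(L - 1, i) = 1.0;
  for (int t = L - 2; t >= 0; --t)
    for (int i = 0; i < m; ++i) {
      double b = 0.0;
      for (int j = 0; j < m; ++j)
        b += T(i, j) * B(j, o[t + 1]) * beta(t + 1, j);
      beta(t, i) = b / c[t + 1];
    }
  for (int t = 0; t < L; ++t) {
    double norm = 0.0;
    for (int i = 0; i < m; ++i) {
      gamma(t, i) = alpha(t, i) * beta(t, i);
      norm += gamma(t, i);
    }
    for (int i = 0; i < m; ++i) gamma(t, i) /= norm;
  }
  return gamma;
}
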