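// Linear-chain CRF: negative log-likelihood + gradient (forward-backward)
// and Viterbi decoding. Parameters are a flat vector: emission weights
// W[f,l] at f*L + l, then transition weights T[a,b] at nFeat*L + a*L + b.
// Features are sparse (index, value) pairs per token; values may be real
// (word-embedding dimensions), not just binary indicators.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double logsumexp(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// node scores S[t][l] for one sentence
static void node_scores(const NumericVector& theta, const List& idx,
                        const List& val, int L,
                        std::vector<std::vector<double> >& S) {
  int T = idx.size();
  S.assign(T, std::vector<double>(L, 0.0));
  for (int t = 0; t < T; ++t) {
    IntegerVector fi = idx[t];
    NumericVector fv = val[t];
    for (int k = 0; k < fi.size(); ++k) {
      int base = fi[k] * L;
      double v = fv[k];
      for (int l = 0; l < L; ++l) S[t][l] += theta[base + l] * v;
    }
  }
}

// [[Rcpp::export]]
List crf_nll_grad(NumericVector theta, List sents, int n_feat, int n_lab) {
  const int L = n_lab;
  const int trans_off = n_feat * L;
  NumericVector grad(theta.size());
  double nll = 0.0;

  for (int s = 0; s < sents.size(); ++s) {
    List sent = sents[s];
    List idx = sent["idx"];
    List val = sent["val"];
    IntegerVector y = sent["y"];
    int T = idx.size();
    if (T == 0) continue;

    std::vector<std::vector<double> > S;
    node_scores(theta, idx, val, L, S);

    // forward
    std::vector<std::vector<double> > alpha(T, std::vector<double>(L));
    for (int l = 0; l < L; ++l) alpha[0][l] = S[0][l];
    std::vector<double> tmp(L);
    for (int t = 1; t < T; ++t)
      for (int l = 0; l < L; ++l) {
        for (int p = 0; p < L; ++p)
          tmp[p] = alpha[t - 1][p] + theta[trans_off + p * L + l];
        alpha[t][l] = S[t][l] + logsumexp(tmp);
      }
    double logZ = logsumexp(alpha[T - 1]);

    // backward
    std::vector<std::vector<double> > beta(T, std::vector<double>(L, 0.0));
    for (int t = T - 2; t >= 0; --t)
      for (int l = 0; l < L; ++l) {
        for (int n = 0; n < L; ++n)
          tmp[n] = theta[trans_off + l * L + n] + S[t + 1][n] + beta[t + 1][n];
        beta[t][l] = logsumexp(tmp);
      }

    // gold score
    double gold = 0.0;
    for (int t = 0; t < T; ++t) {
      gold += S[t][y[t]];
      if (t > 0) gold += theta[trans_off + y[t - 1] * L + y[t]];
    }
    nll += logZ - gold;

    // node marginals -> emission gradient
    for (int t = 0; t < T; ++t) {
      std::vector<double> mu(L);
      for (int l = 0; l < L; ++l)
        mu[l] = std::exp(alpha[t][l] + beta[t][l] - logZ);
      IntegerVector fi = idx[t];
      NumericVector fv = val[t];
      for (int k = 0; k < fi.size(); ++k) {
        int base = fi[k] * L;
        double v = fv[k];
        for (int l = 0; l < L; ++l) grad[base + l] += mu[l] * v;
        grad[base + y[t]] -= v;
      }
    }
    // edge marginals -> transition gradient
    for (int t = 1; t < T; ++t) {
      for (int a = 0; a < L; ++a)
        for (int b = 0; b < L; ++b) {
          double lp = alpha[t - 1][a] + theta[trans_off + a * L + b] +
                      S[t][b] + beta[t][b] - logZ;
          grad[trans_off + a * L + b] += std::exp(lp);
        }
      grad[trans_off + y[t - 1] * L + y[t]] -= 1.0;
    }
  }
  return List::create(Named("nll") = nll, Named("grad") = grad);
}

// [[Rcpp::export]]
IntegerVector crf_viterbi(NumericVector theta, List idx, List val,
                          int n_feat, int n_lab) {
  const int L = n_lab;
  const int trans_off = n_feat * L;
  int T = idx.size();
  IntegerVector path(T);
  if (T == 0) return path;

  std::vector<std::vector<double> > S;
  node_scores(theta, idx, val, L, S);

  std::vector<std::vector<double> > delta(T, std::vector<double>(L));
  std::vector<std::vector<int> > back(T, std::vector<int>(L, 0));
  for (int l = 0; l < L; ++l) delta[0][l] = S[0][l];
  for (int t = 1; t < T; ++t)
    for (int l = 0; l < L; ++l) {
      double best = delta[t - 1][0] + theta[trans_off + 0 * L + l];
      int arg = 0;
      for (int p = 1; p < L; ++p) {
        double sc = delta[t - 1][p] + theta[trans_off + p * L + l];
        if (sc > best) { best = sc; arg = p; }
      }
      delta[t][l] = best + S[t][l];
      back[t][l] = arg;
    }
  int bl = 0;
  for (int l = 1; l < L; ++l) if (delta[T - 1][l] > delta[T - 1][bl]) bl = l;
  path[T - 1] = bl;
  for (int t = T - 1; t > 0; --t) path[t - 1] = back[t][path[t]];
  return path;
}
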