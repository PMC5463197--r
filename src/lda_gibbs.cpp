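#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
// Documents arrive as integer token vectors (0-based word ids); the caller
// expands count vectors into tokens. Uses R's RNG so set.seed() on the R
// side makes runs reproducible.

static double joint_log_lik(const std::vector<std::vector<int> >& nwt,
                            const std::vector<int>& nt,
                            const std::vector<std::vector<int> >& ndt,
                            const std::vector<int>& nd,
                            int K, int M, int D,
                            double alpha, double beta) {
  double ll = K * (std::lgamma(M * beta) - M * std::lgamma(beta));
  for (int t = 0; t < K; ++t) {
    for (int w = 0; w < M; ++w) ll += std::lgamma(nwt[t][w] + beta);
    ll -= std::lgamma(nt[t] + M * beta);
  }
  ll += D * (std::lgamma(K * alpha) - K * std::lgamma(alpha));
  for (int d = 0; d < D; ++d) {
    for (int t = 0; t < K; ++t) ll += std::lgamma(ndt[d][t] + alpha);
    ll -= std::lgamma(nd[d] + K * alpha);
  }
  return ll;
}

// [[Rcpp::export(name = ".lda_gibbs_fit")]]
List lda_gibbs_fit(const List& docs, int M, int K,
                   double alpha, double beta, int iters) {
  const int D = docs.size();
  std::vector<std::vector<int> > tok(D);
  for (int d = 0; d < D; ++d) {
    IntegerVector v = docs[d];
    tok[d].assign(v.begin(), v.end());
  }
  std::vector<std::vector<int> > nwt(K, std::vector<int>(M, 0));
  std::vector<std::vector<int> > ndt(D, std::vector<int>(K, 0));
  std::vector<int> nt(K, 0), nd(D, 0);
  std::vector<std::vector<int> > z(D);

  // random initial assignments
  for (int d = 0; d < D; ++d) {
    const int n = tok[d].size();
    z[d].resize(n);
    for (int i = 0; i < n; ++i) {
      int t = (int)(unif_rand() * K);
      if (t >= K) t = K - 1;
      z[d][i] = t;
      ++nwt[t][tok[d][i]]; ++ndt[d][t]; ++nt[t]; ++nd[d];
    }
  }

  NumericVector loglik(iters);
  std::vector<double> p(K);
  for (int it = 0; it < iters; ++it) {
    for (int d = 0; d < D; ++d) {
      const int n = tok[d].size();
      for (int i = 0; i < n; ++i) {
        const int w = tok[d][i];
        int t = z[d][i];
        --nwt[t][w]; --ndt[d][t]; --nt[t];
        double tot = 0.0;
        for (int u = 0; u < K; ++u) {
          tot += (nwt[u][w] + beta) / (nt[u] + M * beta) * (ndt[d][u] + alpha);
          p[u] = tot;
        }
        const double r = unif_rand() * tot;
        t = 0;
        while (t < K - 1 && p[t] < r) ++t;
        z[d][i] = t;
        ++nwt[t][w]; ++ndt[d][t]; ++nt[t];
      }
    }
    loglik[it] = joint_log_lik(nwt, nt, ndt, nd, K, M, D, alpha, beta);
  }

  NumericMatrix topicWord(K, M), docTopic(D, K);
  for (int t = 0; t < K; ++t)
    for (int w = 0; w < M; ++w)
      topicWord(t, w) = (nwt[t][w] + beta) / (nt[t] + M * beta);
  for (int d = 0; d < D; ++d)
    for (int t = 0; t < K; ++t)
      docTopic(d, t) = (ndt[d][t] + alpha) / (nd[d] + K * alpha);

  List zOut(D);
  for (int d = 0; d < D; ++d) zOut[d] = IntegerVector(z[d].begin(), z[d].end());
  return List::create(_["topic_word"] = topicWord,
                      _["doc_topic"] = docTopic,
                      _["loglik"] = loglik,
                      _["assignments"] = zOut);
}

// Fold-in inference for a single new document with the topic-word matrix
// held fixed; theta averaged over post-burn-in sweeps.

// [[Rcpp::export(name = ".lda_gibbs_transform")]]
NumericVector lda_gibbs_transform(const IntegerVector& tokens,
                                  const NumericMatrix& topicWord,
                                  double alpha, int iters, int burnin) {
  const int K = topicWord.nrow();
  const int n = tokens.size();
  NumericVector theta(K);
  if (n == 0) {
    for (int t = 0; t < K; ++t) theta[t] = 1.0 / K;
    return theta;
  }
  std::vector<int> z(n), ndt(K, 0);
  for (int i = 0; i < n; ++i) {
    int t = (int)(unif_rand() * K);
    if (t >= K) t = K - 1;
    z[i] = t;
    ++ndt[t];
  }
  std::vector<double> p(K), acc(K, 0.0);
  int kept = 0;
  for (int it = 0; it < iters; ++it) {
    for (int i = 0; i < n; ++i) {
      const int w = tokens[i];
      int t = z[i];
      --ndt[t];
      double tot = 0.0;
      for (int u = 0; u < K; ++u) {
        tot += topicWord(u, w) * (ndt[u] + alpha);
        p[u] = tot;
      }
      const double r = unif_rand() * tot;
      t = 0;
      while (t < K - 1 && p[t] < r) ++t;
      z[i] = t;
      ++ndt[t];
    }
    if (it >= burnin) {
      for (int t = 0; t < K; ++t) acc[t] += (ndt[t] + alpha) / (n + K * alpha);
      ++kept;
    }
  }
  double s = 0.0;
  for (int t = 0; t < K; ++t) { theta[t] = acc[t] / kept; s += theta[t]; }
  for (int t = 0; t < K; ++t) theta[t] /= s;
  return theta;
}
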