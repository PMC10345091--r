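#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA with samples as documents and omic
// features as words. counts is V x D (features x samples) of nonnegative
// integers; tokens are the count-expanded words. Uses R's RNG so that
// set.seed() in R fixes the chain. theta/beta are posterior means of the
// smoothed count ratios averaged over post-burn-in sweeps (every `thin`).
// [[Rcpp::export]]
List gibbs_lda_cpp(IntegerMatrix counts, int K, double alpha, double gamma,
                   int n_iter, int burn_in, int thin, bool debug) {
  const int V = counts.nrow();
  const int D = counts.ncol();

  // token expansion
  std::vector<int> tok_word, tok_doc;
  for (int d = 0; d < D; ++d)
    for (int v = 0; v < V; ++v)
      for (int c = 0; c < counts(v, d); ++c) {
        tok_word.push_back(v);
        tok_doc.push_back(d);
      }
  const int N = (int)tok_word.size();
  if (N == 0) stop("no tokens: all counts are zero");

  std::vector<int> z(N);
  std::vector<int> ndk(D * K, 0);   // doc-topic
  std::vector<int> nkv(K * V, 0);   // topic-word
  std::vector<int> nk(K, 0);        // topic totals
  std::vector<double> p(K);

  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[i] = k;
    ++ndk[tok_doc[i] * K + k];
    ++nkv[k * V + tok_word[i]];
    ++nk[k];
  }

  const double Vg = V * gamma;
  NumericMatrix theta_sum(D, K), beta_sum(K, V);
  int n_saved = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    for (int i = 0; i < N; ++i) {
      const int d = tok_doc[i], v = tok_word[i];
      int k = z[i];
      --ndk[d * K + k]; --nkv[k * V + v]; --nk[k];

      double tot = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        tot += (ndk[d * K + kk] + alpha) *
               (nkv[kk * V + v] + gamma) / (nk[kk] + Vg);
        p[kk] = tot;
      }
      const double u = unif_rand() * tot;
      k = 0;
      while (k < K - 1 && p[k] < u) ++k;

      z[i] = k;
      ++ndk[d * K + k]; ++nkv[k * V + v]; ++nk[k];
    }

    if (debug) { // cache consistency after every sweep
      std::vector<int> chk(K, 0);
      for (int i = 0; i < N; ++i) ++chk[z[i]];
      for (int k = 0; k < K; ++k)
        if (chk[k] != nk[k]) stop("gibbs cache inconsistent at sweep %d", iter);
    }

    if (iter > burn_in && ((iter - burn_in) % thin == 0)) {
      ++n_saved;
      for (int d = 0; d < D; ++d) {
        double Nd = 0;
        for (int k = 0; k < K; ++k) Nd += ndk[d * K + k];
        for (int k = 0; k < K; ++k)
          theta_sum(d, k) += (ndk[d * K + k] + alpha) / (Nd + K * alpha);
      }
      for (int k = 0; k < K; ++k)
        for (int v = 0; v < V; ++v)
          beta_sum(k, v) += (nkv[k * V + v] + gamma) / (nk[k] + Vg);
    }
  }
  if (n_saved == 0) stop("no post-burn-in samples saved; check iterations/thin");

  NumericMatrix theta(D, K), beta(K, V);
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) theta(d, k) = theta_sum(d, k) / n_saved;
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v) beta(k, v) = beta_sum(k, v) / n_saved;

  return List::create(_["theta"] = theta, _["beta"] = beta,
                      _["n_saved"] = n_saved, _["n_tokens"] = N);
}
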