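#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs sampler for the standard LDA model with symmetric
// Dirichlet priors (alpha on document-topic, beta on topic-word).
//
// docs: list of integer vectors of 0-based token ids (each non-empty).
// Returns final-state phi (K x V) and theta (D x K) with Dirichlet
// smoothing, plus (optionally) the per-sweep token assignment trace for
// sweeps after `burnin` so small problems can be checked against
// exhaustive enumeration of the collapsed posterior.
//
// All randomness comes from a std::mt19937 seeded with `seed`, so runs
// are reproducible across platforms independent of R's RNG state.
// [[Rcpp::export]]
List lda_gibbs_cpp(const List& docs, const int V, const int K,
                   const double alpha, const double beta,
                   const int n_iter, const int burnin,
                   const int seed, const bool keep_samples) {
  const int D = docs.size();
  std::vector<int> tok_w, tok_d;
  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    for (int i = 0; i < doc.size(); ++i) {
      tok_w.push_back(doc[i]);
      tok_d.push_back(d);
    }
  }
  const int N = (int)tok_w.size();

  std::mt19937 rng((uint32_t)seed);
  auto runif01 = [&rng]() {
    // 32 random bits -> [0, 1); deterministic across platforms
    return (double)rng() / 4294967296.0;
  };

  std::vector<int> z(N);
  std::vector<int> nkw((size_t)K * V, 0), nk(K, 0), ndk((size_t)D * K, 0);
  for (int i = 0; i < N; ++i) {
    int k = (int)(runif01() * K);
    if (k == K) k = K - 1;
    z[i] = k;
    ++nkw[(size_t)k * V + tok_w[i]];
    ++nk[k];
    ++ndk[(size_t)tok_d[i] * K + k];
  }

  const double Vbeta = V * beta;
  std::vector<double> p(K);
  const int n_kept = keep_samples ? std::max(0, n_iter - burnin) : 0;
  IntegerMatrix trace(n_kept, keep_samples ? N : 0);

  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      const int w = tok_w[i], d = tok_d[i], old = z[i];
      --nkw[(size_t)old * V + w];
      --nk[old];
      --ndk[(size_t)d * K + old];
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        tot += (ndk[(size_t)d * K + k] + alpha) *
               (nkw[(size_t)k * V + w] + beta) / (nk[k] + Vbeta);
        p[k] = tot;
      }
      const double u = runif01() * tot;
      int k = 0;
      while (k < K - 1 && p[k] < u) ++k;
      z[i] = k;
      ++nkw[(size_t)k * V + w];
      ++nk[k];
      ++ndk[(size_t)d * K + k];
    }
    if (keep_samples && it >= burnin) {
      for (int i = 0; i < N; ++i) trace(it - burnin, i) = z[i];
    }
  }

  NumericMatrix phi(K, V), theta(D, K);
  for (int k = 0; k < K; ++k)
    for (int w = 0; w < V; ++w)
      phi(k, w) = (nkw[(size_t)k * V + w] + beta) / (nk[k] + Vbeta);
  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    const double nd = doc.size();
    for (int k = 0; k < K; ++k)
      theta(d, k) = (ndk[(size_t)d * K + k] + alpha) / (nd + K * alpha);
  }

  // collapsed joint log probability of the final state (up to an additive
  // constant shared by all states of this corpus/prior): used to pick the
  // best of several restarts
  double ll = 0.0;
  for (int k = 0; k < K; ++k) {
    for (int w = 0; w < V; ++w) ll += std::lgamma(nkw[(size_t)k * V + w] + beta);
    ll -= std::lgamma(nk[k] + Vbeta);
  }
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) ll += std::lgamma(ndk[(size_t)d * K + k] + alpha);

  List out = List::create(_["phi"] = phi, _["theta"] = theta,
                          _["log_posterior"] = ll);
  if (keep_samples) out["samples"] = trace;
  return out;
}
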