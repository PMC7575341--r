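// Collapsed Gibbs sampler for a Dirichlet-prior topic model.
// Deterministic given the seed: uses its own mt19937 stream, never R's RNG.
#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// tokens: 0-based term ids, doc_ptr: CSR-style offsets (length D+1)
// [[Rcpp::export(name = ".lda_gibbs")]]
List lda_gibbs(IntegerVector tokens, IntegerVector doc_ptr, int V, int K,
               double alpha, double beta, int n_iter, int burnin, int seed) {
  const int N = tokens.size();
  const int D = doc_ptr.size() - 1;
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> z(N);
  std::vector<double> ndk(static_cast<size_t>(D) * K, 0.0);
  std::vector<double> nkw(static_cast<size_t>(K) * V, 0.0);
  std::vector<double> nk(K, 0.0);

  for (int d = 0; d < D; ++d) {
    for (int i = doc_ptr[d]; i < doc_ptr[d + 1]; ++i) {
      int t = static_cast<int>(std::floor(unif(rng) * K));
      if (t == K) t = K - 1;
      z[i] = t;
      ndk[static_cast<size_t>(d) * K + t] += 1.0;
      nkw[static_cast<size_t>(t) * V + tokens[i]] += 1.0;
      nk[t] += 1.0;
    }
  }

  // accumulated posterior means over post-burnin sweeps
  std::vector<double> phi_acc(static_cast<size_t>(K) * V, 0.0);
  std::vector<double> theta_acc(static_cast<size_t>(D) * K, 0.0);
  int n_acc = 0;
  std::vector<double> prob(K);

  for (int it = 0; it < n_iter; ++it) {
    for (int d = 0; d < D; ++d) {
      const size_t dK = static_cast<size_t>(d) * K;
      for (int i = doc_ptr[d]; i < doc_ptr[d + 1]; ++i) {
        const int w = tokens[i];
        const int old = z[i];
        ndk[dK + old] -= 1.0;
        nkw[static_cast<size_t>(old) * V + w] -= 1.0;
        nk[old] -= 1.0;
        double tot = 0.0;
        for (int t = 0; t < K; ++t) {
          double p = (ndk[dK + t] + alpha) *
                     (nkw[static_cast<size_t>(t) * V + w] + beta) /
                     (nk[t] + V * beta);
          tot += p;
          prob[t] = tot;
        }
        double u = unif(rng) * tot;
        int t_new = 0;
        while (t_new < K - 1 && prob[t_new] < u) ++t_new;
        z[i] = t_new;
        ndk[dK + t_new] += 1.0;
        nkw[static_cast<size_t>(t_new) * V + w] += 1.0;
        nk[t_new] += 1.0;
      }
    }
    if (it >= burnin) {
      ++n_acc;
      for (size_t j = 0; j < phi_acc.size(); ++j) {
        int t = static_cast<int>(j / V);
        phi_acc[j] += (nkw[j] + beta) / (nk[t] + V * beta);
      }
      for (int d = 0; d < D; ++d) {
        const size_t dK = static_cast<size_t>(d) * K;
        double nd = doc_ptr[d + 1] - doc_ptr[d];
        for (int t = 0; t < K; ++t) {
          theta_acc[dK + t] += (ndk[dK + t] + alpha) / (nd + K * alpha);
        }
      }
    }
  }
  if (n_acc == 0) n_acc = 1;

  NumericMatrix phi(K, V);
  for (int t = 0; t < K; ++t) {
    double rs = 0.0;
    for (int w = 0; w < V; ++w) rs += phi_acc[static_cast<size_t>(t) * V + w];
    for (int w = 0; w < V; ++w) {
      phi(t, w) = phi_acc[static_cast<size_t>(t) * V + w] / rs;
    }
  }
  NumericMatrix theta(D, K);
  for (int d = 0; d < D; ++d) {
    double rs = 0.0;
    for (int t = 0; t < K; ++t) rs += theta_acc[static_cast<size_t>(d) * K + t];
    for (int t = 0; t < K; ++t) {
      theta(d, t) = theta_acc[static_cast<size_t>(d) * K + t] / rs;
    }
  }
  return List::create(_["phi"] = phi, _["theta"] = theta);
}
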