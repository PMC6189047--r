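// Single-threaded word2vec-style trainer (CBOW / skip-gram with negative
// sampling) over integer-encoded k-mer sentences. Runs on its own RNG so a
// fixed seed reproduces the matrix exactly. Token index 0 marks OOV and is
// skipped; vocabulary indices are 1..V.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

struct Xorshift {
  uint64_t s;
  explicit Xorshift(uint64_t seed) : s(seed * 2685821657736338717ULL + 1ULL) {
    if (s == 0) s = 88172645463325252ULL;
  }
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) {
    int r = static_cast<int>(unif() * n);
    return r >= n ? n - 1 : r;
  }
};

inline double fast_sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Draw one index from the count^0.75 unigram distribution via binary
// search on the cumulative table. Returns 1..V.
inline int sample_negative(const std::vector<double>& cum, Xorshift& rng) {
  double u = rng.unif() * cum.back();
  int lo = 0, hi = static_cast<int>(cum.size()) - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo + 1;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_train_word2vec(List sentences, int V, int d, int window,
                                 int epochs, int negative, double alpha,
                                 bool cbow, int seed) {
  Xorshift rng(static_cast<uint64_t>(seed) + 0x9E3779B97F4A7C15ULL);

  // syn0: input (word) vectors; syn1: output vectors for negative sampling.
  std::vector<double> syn0(static_cast<size_t>(V) * d);
  std::vector<double> syn1(static_cast<size_t>(V) * d, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / d;

  const int n_sent = sentences.size();
  std::vector<std::vector<int> > corpus(n_sent);
  std::vector<double> counts(V, 0.0);
  long long total_tokens = 0;
  for (int i = 0; i < n_sent; ++i) {
    IntegerVector s = sentences[i];
    corpus[i].assign(s.begin(), s.end());
    for (int j = 0; j < s.size(); ++j) {
      if (s[j] >= 1 && s[j] <= V) {
        counts[s[j] - 1] += 1.0;
        ++total_tokens;
      }
    }
  }

  NumericMatrix out(V, d);
  if (total_tokens == 0) {  // nothing to train on; return the random init
    for (int i = 0; i < V; ++i)
      for (int j = 0; j < d; ++j) out(i, j) = syn0[static_cast<size_t>(i) * d + j];
    return out;
  }

  std::vector<double> cum(V);
  double acc = 0.0;
  for (int i = 0; i < V; ++i) {
    acc += std::pow(counts[i], 0.75);
    cum[i] = acc;
  }

  const double alpha_min = alpha * 1e-4;
  const double planned = static_cast<double>(total_tokens) * epochs;
  long long trained = 0;
  std::vector<double> neu1(d), neu1e(d);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int si = 0; si < n_sent; ++si) {
      const std::vector<int>& sent = corpus[si];
      const int n = static_cast<int>(sent.size());
      for (int t = 0; t < n; ++t) {
        const int w = sent[t];
        if (w < 1 || w > V) continue;
        double lr = alpha * (1.0 - static_cast<double>(trained) / (planned + 1.0));
        if (lr < alpha_min) lr = alpha_min;
        ++trained;
        const int b = 1 + rng.below(window);  // reduced window in 1..window

        if (cbow) {
          std::fill(neu1.begin(), neu1.end(), 0.0);
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          int cw = 0;
          for (int c = t - b; c <= t + b; ++c) {
            if (c == t || c < 0 || c >= n) continue;
            const int u = sent[c];
            if (u < 1 || u > V) continue;
            const double* v = &syn0[static_cast<size_t>(u - 1) * d];
            for (int j = 0; j < d; ++j) neu1[j] += v[j];
            ++cw;
          }
          if (cw == 0) continue;
          for (int j = 0; j < d; ++j) neu1[j] /= cw;
          for (int nsample = 0; nsample <= negative; ++nsample) {
            int target;
            double label;
            if (nsample == 0) {
              target = w;
              label = 1.0;
            } else {
              target = sample_negative(cum, rng);
              if (target == w) continue;
              label = 0.0;
            }
            double* o = &syn1[static_cast<size_t>(target - 1) * d];
            double f = 0.0;
            for (int j = 0; j < d; ++j) f += neu1[j] * o[j];
            const double g = (label - fast_sigmoid(f)) * lr;
            for (int j = 0; j < d; ++j) {
              neu1e[j] += g * o[j];
              o[j] += g * neu1[j];
            }
          }
          for (int c = t - b; c <= t + b; ++c) {
            if (c == t || c < 0 || c >= n) continue;
            const int u = sent[c];
            if (u < 1 || u > V) continue;
            double* v = &syn0[static_cast<size_t>(u - 1) * d];
            for (int j = 0; j < d; ++j) v[j] += neu1e[j];
          }
        } else {  // skip-gram
          for (int c = t - b; c <= t + b; ++c) {
            if (c == t || c < 0 || c >= n) continue;
            const int u = sent[c];
            if (u < 1 || u > V) continue;
            double* v = &syn0[static_cast<size_t>(u - 1) * d];
            std::fill(neu1e.begin(), neu1e.end(), 0.0);
            for (int nsample = 0; nsample <= negative; ++nsample) {
              int target;
              double label;
              if (nsample == 0) {
                target = w;
                label = 1.0;
              } else {
                target = sample_negative(cum, rng);
                if (target == w) continue;
                label = 0.0;
              }
              double* o = &syn1[static_cast<size_t>(target - 1) * d];
              double f = 0.0;
              for (int j = 0; j < d; ++j) f += v[j] * o[j];
              const double g = (label - fast_sigmoid(f)) * lr;
              for (int j = 0; j < d; ++j) {
                neu1e[j] += g * o[j];
                o[j] += g * v[j];
              }
            }
            for (int j = 0; j < d; ++j) v[j] += neu1e[j];
          }
        }
      }
    }
  }

  for (int i = 0; i < V; ++i)
    for (int j = 0; j < d; ++j) out(i, j) = syn0[static_cast<size_t>(i) * d + j];
  return out;
}
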