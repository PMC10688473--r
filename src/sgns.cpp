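#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// xorshift64* generator: embedding training must be reproducible from an
// integer seed independent of R's RNG state
static inline uint64_t xorshift(uint64_t &s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 2685821657736338717ULL;
}
static inline double runif01(uint64_t &s) {
  return (xorshift(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over a corpus of walks.
// walks: list of integer vectors with 1-based node ids in 1..vocab.
// Returns vocab x dim matrix of input vectors.
// [[Rcpp::export]]
NumericMatrix sgns_train(List walks, int vocab, int dim, int window,
                         int negative, int epochs, double alpha,
                         double alpha_min, int seed) {
  uint64_t rng = static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL;
  xorshift(rng);

  // unigram^0.75 negative-sampling table
  std::vector<double> counts(vocab, 0.0);
  long long total_tokens = 0;
  for (int w = 0; w < walks.size(); ++w) {
    IntegerVector wk = walks[w];
    total_tokens += wk.size();
    for (int t = 0; t < wk.size(); ++t) counts[wk[t] - 1] += 1.0;
  }
  const int table_size = 1 << 17;
  std::vector<int> neg_table(table_size);
  double z = 0.0;
  for (int v = 0; v < vocab; ++v) z += std::pow(counts[v], 0.75);
  {
    double cum = 0.0;
    int v = 0;
    double p = std::pow(counts[0], 0.75) / z;
    cum = p;
    for (int i = 0; i < table_size; ++i) {
      double frac = (i + 1.0) / table_size;
      while (frac > cum && v < vocab - 1) {
        ++v;
        cum += std::pow(counts[v], 0.75) / z;
      }
      neg_table[i] = v;
    }
  }

  std::vector<double> syn0(static_cast<size_t>(vocab) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (runif01(rng) - 0.5) / dim;

  long long processed = 0;
  const long long planned = static_cast<long long>(epochs) * total_tokens;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < walks.size(); ++w) {
      IntegerVector wk = walks[w];
      int len = wk.size();
      for (int t = 0; t < len; ++t) {
        double lr = alpha + (alpha_min - alpha) *
          (static_cast<double>(processed) / std::max(planned, 1LL));
        ++processed;
        int center = wk[t] - 1;
        // dynamic window as in word2vec
        int b = static_cast<int>(runif01(rng) * window);
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          int cpos = t + off;
          if (cpos < 0 || cpos >= len) continue;
          int context = wk[cpos] - 1;
          double *v_in = &syn0[static_cast<size_t>(context) * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = center;
              label = 1.0;
            } else {
              target = neg_table[xorshift(rng) % table_size];
              if (target == center) continue;
              label = 0.0;
            }
            double *v_out = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v_in[d] * v_out[d];
            double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int v = 0; v < vocab; ++v)
    for (int d = 0; d < dim; ++d)
      out(v, d) = syn0[static_cast<size_t>(v) * dim + d];
  return out;
}
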