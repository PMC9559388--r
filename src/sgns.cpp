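#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Skip-gram with negative sampling over pre-tokenised integer sentences.
// Single-threaded on purpose: results are bit-reproducible for a given seed.

namespace {

struct Lcg {
  unsigned long long state;
  explicit Lcg(unsigned long long s) : state(s) {}
  unsigned long long next() {
    state = state * 25214903917ULL + 11ULL;
    return state;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 16 & 0xFFFFFFFFULL) / 4294967296.0; }
  int below(int n) {
    return (int)((next() >> 16 & 0xFFFFFFFFULL) % (unsigned long long)n);
  }
};

const int kTableSize = 1 << 20;

}  // namespace

// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List corpus, int vocab_size, NumericVector counts,
                             int dim, int window, int epochs, int negative,
                             double alpha, double seed) {
  Lcg rng((unsigned long long)seed * 2862933555777941757ULL + 3037000493ULL);

  std::vector<float> syn0((size_t)vocab_size * dim);
  std::vector<float> syn1((size_t)vocab_size * dim, 0.0f);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (float)((rng.unif() - 0.5) / dim);

  // unigram^0.75 table for negative sampling
  std::vector<int> table(kTableSize);
  double total = 0.0;
  for (int v = 0; v < vocab_size; ++v) total += std::pow(counts[v], 0.75);
  {
    int v = 0;
    double cum = std::pow(counts[0], 0.75) / total;
    for (int i = 0; i < kTableSize; ++i) {
      table[i] = v;
      if ((i + 1.0) / kTableSize > cum && v < vocab_size - 1) {
        ++v;
        cum += std::pow(counts[v], 0.75) / total;
      }
    }
  }

  long long total_tokens = 0;
  int n_sent = corpus.size();
  std::vector<std::vector<int>> sents(n_sent);
  for (int s = 0; s < n_sent; ++s) {
    IntegerVector iv = corpus[s];
    sents[s].assign(iv.begin(), iv.end());
    for (int &w : sents[s]) --w;  // to 0-based
    total_tokens += sents[s].size();
  }
  const long long train_total = total_tokens * (long long)epochs;
  const double min_alpha = alpha * 1e-4;

  std::vector<float> grad(dim);
  long long seen = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const std::vector<int> &sent = sents[s];
      const int len = (int)sent.size();
      for (int pos = 0; pos < len; ++pos) {
        ++seen;
        double lr = alpha * (1.0 - (double)seen / (train_total + 1));
        if (lr < min_alpha) lr = min_alpha;
        const int b = rng.below(window);  // reduced window
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          const int cpos = pos + off;
          if (cpos < 0 || cpos >= len) continue;
          const int win = sent[cpos];   // input word
          const int wout = sent[pos];   // predicted word
          float *v_in = &syn0[(size_t)win * dim];
          std::fill(grad.begin(), grad.end(), 0.0f);
          for (int d = 0; d <= negative; ++d) {
            int target;
            float label;
            if (d == 0) {
              target = wout;
              label = 1.0f;
            } else {
              target = table[rng.below(kTableSize)];
              // skip both pair members: with small vocabularies,
              // self-negatives otherwise anti-align co-occurring tokens
              if (target == wout || target == win) continue;
              label = 0.0f;
            }
            float *v_out = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += v_in[k] * v_out[k];
            double g;  // (label - sigmoid(f)) * lr, with hard clipping
            if (f > 6.0)
              g = (label - 1.0) * lr;
            else if (f < -6.0)
              g = (double)label * lr;
            else
              g = (label - 1.0 / (1.0 + std::exp(-f))) * lr;
            for (int k = 0; k < dim; ++k) grad[k] += (float)g * v_out[k];
            for (int k = 0; k < dim; ++k) v_out[k] += (float)g * v_in[k];
          }
          for (int k = 0; k < dim; ++k) v_in[k] += grad[k];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int k = 0; k < dim; ++k) out(v, k) = syn0[(size_t)v * dim + k];
  return out;
}
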