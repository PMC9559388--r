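#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Second-order biased random walks (return parameter p, in-out parameter q)
// on a weighted undirected graph in CSR form. Edge weights multiply the
// p/q bias. Cumulative-sum inverse sampling; deterministic for a given seed.

namespace {
struct Lcg {
  unsigned long long state;
  explicit Lcg(unsigned long long s) : state(s) {}
  double unif() {
    state = state * 25214903917ULL + 11ULL;
    return (state >> 16 & 0xFFFFFFFFULL) / 4294967296.0;
  }
};

inline bool adjacent(const IntegerVector &ptr, const IntegerVector &idx,
                     int t, int x) {
  const int *lo = &idx[0] + ptr[t];
  const int *hi = &idx[0] + ptr[t + 1];
  return std::binary_search(lo, hi, x);
}
}  // namespace

// [[Rcpp::export]]
List generate_walks_cpp(IntegerVector adj_ptr, IntegerVector adj_idx,
                        NumericVector adj_w, int n_nodes, double p, double q,
                        int walk_length, int walks_per_node, double seed) {
  Lcg rng((unsigned long long)seed * 6364136223846793005ULL + 1442695040888963407ULL);
  List out(n_nodes * walks_per_node);
  std::vector<double> cum;
  int wi = 0;
  for (int r = 0; r < walks_per_node; ++r) {
    for (int src = 0; src < n_nodes; ++src) {
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(src);
      int prev = -1, cur = src;
      while ((int)walk.size() < walk_length) {
        const int beg = adj_ptr[cur], end = adj_ptr[cur + 1];
        const int deg = end - beg;
        if (deg == 0) break;  // isolated node: length-1 walk
        cum.resize(deg);
        double tot = 0.0;
        for (int j = 0; j < deg; ++j) {
          const int x = adj_idx[beg + j];
          double a;
          if (prev < 0)
            a = 1.0;  // first step: weight only
          else if (x == prev)
            a = 1.0 / p;
          else if (adjacent(adj_ptr, adj_idx, prev, x))
            a = 1.0;
          else
            a = 1.0 / q;
          tot += a * adj_w[beg + j];
          cum[j] = tot;
        }
        const double u = rng.unif() * tot;
        int j = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
        if (j >= deg) j = deg - 1;
        prev = cur;
        cur = adj_idx[beg + j];
        walk.push_back(cur);
      }
      IntegerVector w(walk.size());
      for (size_t k = 0; k < walk.size(); ++k) w[k] = walk[k] + 1;  // 1-based
      out[wi++] = w;
    }
  }
  return out;
}
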