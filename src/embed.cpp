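// Random-walk embedding core: weighted walks, skip-gram with negative
// sampling, and a cross-entropy 2-D layout optimizer. Single-threaded and
// driven by an internal xorshift RNG so results are reproducible for a seed.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int below(int n) { return static_cast<int>(unif() * n); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// binary search in a cumulative-weight vector restricted to [lo, hi)
inline int cum_search(const std::vector<double>& cum, int lo, int hi, double u) {
  int l = lo, r = hi - 1;
  while (l < r) {
    int m = (l + r) / 2;
    if (cum[m] < u) l = m + 1; else r = m;
  }
  return l;
}

}  // namespace

// Weighted first-order random walks over a CSR graph. indptr/indices are
// 0-based; weights align with indices. Returns an (n_nodes * num_walks) x
// walk_length integer matrix of 0-based node ids.
// [[Rcpp::export]]
IntegerMatrix cpp_random_walks(IntegerVector indptr, IntegerVector indices,
                               NumericVector weights, int num_walks,
                               int walk_length, double seed) {
  const int n = indptr.size() - 1;
  XorShift64 rng(static_cast<uint64_t>(seed));

  // per-edge cumulative weights within each node's slab
  std::vector<double> cum(indices.size());
  for (int v = 0; v < n; ++v) {
    double acc = 0.0;
    for (int k = indptr[v]; k < indptr[v + 1]; ++k) {
      acc += weights[k];
      cum[k] = acc;
    }
  }

  IntegerMatrix walks(n * num_walks, walk_length);
  int row = 0;
  for (int w = 0; w < num_walks; ++w) {
    for (int start = 0; start < n; ++start, ++row) {
      int cur = start;
      walks(row, 0) = cur;
      for (int step = 1; step < walk_length; ++step) {
        int lo = indptr[cur], hi = indptr[cur + 1];
        if (lo == hi) {  // dead end: stay put (prevented upstream)
          walks(row, step) = cur;
          continue;
        }
        double total = cum[hi - 1];
        int k = cum_search(cum, lo, hi, rng.unif() * total);
        cur = indices[k];
        walks(row, step) = cur;
      }
    }
  }
  return walks;
}

// Skip-gram with negative sampling over walk corpora. Negative nodes are
// drawn from the unigram distribution raised to 0.75. Learning rate decays
// linearly. Returns the n_nodes x dim input-vector matrix.
// [[Rcpp::export]]
NumericMatrix cpp_sgns(IntegerMatrix walks, int n_nodes, int dim, int window,
                       int negative, int epochs, double alpha0, double seed) {
  const int n_walks = walks.nrow(), wl = walks.ncol();
  XorShift64 rng(static_cast<uint64_t>(seed) * 2862933555777941757ULL + 3037000493ULL);

  // unigram^0.75 cumulative table
  std::vector<double> freq(n_nodes, 0.0);
  for (int i = 0; i < n_walks; ++i)
    for (int j = 0; j < wl; ++j) freq[walks(i, j)] += 1.0;
  std::vector<double> negcum(n_nodes);
  double acc = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    acc += std::pow(freq[v], 0.75);
    negcum[v] = acc;
  }
  const double negtot = acc;

  // init: input vectors small uniform, output vectors zero (word2vec style)
  std::vector<double> vin(static_cast<size_t>(n_nodes) * dim);
  std::vector<double> vout(static_cast<size_t>(n_nodes) * dim, 0.0);
  for (size_t i = 0; i < vin.size(); ++i)
    vin[i] = (rng.unif() - 0.5) / dim;

  const double total_tokens =
      static_cast<double>(epochs) * n_walks * wl;
  double processed = 0.0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < n_walks; ++i) {
      for (int j = 0; j < wl; ++j, processed += 1.0) {
        double alpha = alpha0 * (1.0 - processed / (total_tokens + 1.0));
        if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
        const int center = walks(i, j);
        const int b = 1 + rng.below(window);  // dynamic window
        for (int c = j - b; c <= j + b; ++c) {
          if (c == j || c < 0 || c >= wl) continue;
          const int context = walks(i, c);
          double* vc = &vin[static_cast<size_t>(context) * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = center;
              label = 1.0;
            } else {
              target = cum_search(negcum, 0, n_nodes, rng.unif() * negtot);
              if (target == center) continue;
              label = 0.0;
            }
            double* vt = &vout[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += vc[d] * vt[d];
            const double g = (label - sigmoid(dot)) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * vt[d];
              vt[d] += g * vc[d];
            }
          }
          for (int d = 0; d < dim; ++d) vc[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v)
    for (int d = 0; d < dim; ++d) out(v, d) = vin[static_cast<size_t>(v) * dim + d];
  return out;
}

// Stochastic-gradient layout for a fuzzy k-nearest-neighbour graph:
// attraction along weighted edges, repulsion against sampled non-neighbours,
// using the 1/(1 + a d^(2b)) low-dimensional kernel.
// [[Rcpp::export]]
NumericMatrix cpp_umap_layout(NumericMatrix init, IntegerVector head,
                              IntegerVector tail, NumericVector weight,
                              double a, double b, int n_epochs,
                              int neg_samples, double alpha0, double seed) {
  const int n = init.nrow();
  const int n_edges = head.size();
  XorShift64 rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL);

  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = init(i, 0); y[i] = init(i, 1); }

  double wmax = 0.0;
  for (int e = 0; e < n_edges; ++e) if (weight[e] > wmax) wmax = weight[e];
  if (wmax <= 0) wmax = 1.0;

  const double clip = 4.0;
  auto clamp = [&](double v) { return v > clip ? clip : (v < -clip ? -clip : v); };

  for (int ep = 0; ep < n_epochs; ++ep) {
    const double alpha = alpha0 * (1.0 - static_cast<double>(ep) / n_epochs);
    for (int e = 0; e < n_edges; ++e) {
      if (rng.unif() > weight[e] / wmax) continue;  // sample edge by weight
      const int i = head[e], j = tail[e];
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      // attractive gradient of log(1/(1+a d^{2b}))
      double gcoef = 0.0;
      if (d2 > 0.0) {
        const double pd = std::pow(d2, b);
        gcoef = (-2.0 * a * b * pd / d2) / (1.0 + a * pd);
      }
      double gx = clamp(gcoef * dx) * alpha, gy = clamp(gcoef * dy) * alpha;
      x[i] += gx; y[i] += gy;
      x[j] -= gx; y[j] -= gy;
      for (int s = 0; s < neg_samples; ++s) {
        const int k = rng.below(n);
        if (k == i) continue;
        dx = x[i] - x[k]; dy = y[i] - y[k];
        d2 = dx * dx + dy * dy;
        double rcoef;
        if (d2 > 0.0)
          rcoef = (2.0 * b) / ((0.001 + d2) * (1.0 + a * std::pow(d2, b)));
        else
          rcoef = clip;
        x[i] += clamp(rcoef * dx) * alpha;
        y[i] += clamp(rcoef * dy) * alpha;
      }
    }
  }

  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; }
  return out;
}
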