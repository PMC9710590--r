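// Random-walk and skip-gram kernels for the graph-based embedding (E3).
// Single-threaded and seeded for exact reproducibility.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

static inline bool is_neighbor(const std::vector<int>& sorted, int x) {
  return std::binary_search(sorted.begin(), sorted.end(), x);
}

// node2vec second-order random walks. adj: list of sorted 1-based neighbor
// vectors. Returns (n_nodes * walks_per_node) x walk_length matrix of
// 1-based node ids, 0-padded where a walk terminates early (isolated node).
// [[Rcpp::export]]
IntegerMatrix cpp_node2vec_walks(List adj, int walk_length,
                                 int walks_per_node, double p, double q,
                                 int seed) {
  int n = adj.size();
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    nb[i] = std::vector<int>(v.begin(), v.end());
    std::sort(nb[i].begin(), nb[i].end());
  }
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  IntegerMatrix walks(n * walks_per_node, walk_length);
  std::vector<double> w;
  int row = 0;
  for (int w_i = 0; w_i < walks_per_node; ++w_i) {
    for (int start = 1; start <= n; ++start, ++row) {
      walks(row, 0) = start;
      int cur = start, prev = -1;
      for (int step = 1; step < walk_length; ++step) {
        const std::vector<int>& cn = nb[cur - 1];
        if (cn.empty()) break;
        int nxt;
        if (prev < 0 || (p == 1.0 && q == 1.0)) {
          nxt = cn[(size_t)(unif(rng) * cn.size()) % cn.size()];
        } else {
          w.resize(cn.size());
          double tot = 0.0;
          for (size_t t = 0; t < cn.size(); ++t) {
            double wt;
            if (cn[t] == prev) wt = 1.0 / p;
            else if (is_neighbor(nb[prev - 1], cn[t])) wt = 1.0;
            else wt = 1.0 / q;
            tot += wt;
            w[t] = tot;
          }
          double r = unif(rng) * tot;
          size_t t = std::lower_bound(w.begin(), w.end(), r) - w.begin();
          if (t >= cn.size()) t = cn.size() - 1;
          nxt = cn[t];
        }
        walks(row, step) = nxt;
        prev = cur;
        cur = nxt;
      }
    }
  }
  return walks;
}

// Skip-gram with negative sampling over integer walks (word2vec-style,
// dynamic window, linearly decaying learning rate, unigram^0.75 negative
// table). Returns the input-vector matrix (n_nodes x dim).
// [[Rcpp::export]]
NumericMatrix cpp_skipgram_train(IntegerMatrix walks, int n_nodes, int dim,
                                 int window, int negative, int epochs,
                                 double alpha, int seed) {
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // unigram counts -> cumulative table with 0.75 smoothing
  std::vector<double> cnt(n_nodes, 0.0);
  long long total_tokens = 0;
  for (int r = 0; r < walks.nrow(); ++r)
    for (int c = 0; c < walks.ncol(); ++c)
      if (walks(r, c) > 0) { cnt[walks(r, c) - 1] += 1.0; ++total_tokens; }
  std::vector<double> cum(n_nodes);
  double tot = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    tot += std::pow(cnt[i], 0.75);
    cum[i] = tot;
  }

  std::vector<double> syn0((size_t)n_nodes * dim), syn1((size_t)n_nodes * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif(rng) - 0.5) / dim;

  const double min_alpha_frac = 1e-4;
  long long processed = 0;
  long long planned = (long long)total_tokens * epochs;
  std::vector<double> grad(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int r = 0; r < walks.nrow(); ++r) {
      int len = 0;
      while (len < walks.ncol() && walks(r, len) > 0) ++len;
      for (int pos = 0; pos < len; ++pos) {
        double lr = alpha * (1.0 - (double)processed / (double)(planned + 1));
        if (lr < alpha * min_alpha_frac) lr = alpha * min_alpha_frac;
        ++processed;
        int center = walks(r, pos) - 1;
        int b = (int)(unif(rng) * window);  // dynamic window shrink
        for (int off = -(window - b); off <= window - b; ++off) {
          if (off == 0) continue;
          int cpos = pos + off;
          if (cpos < 0 || cpos >= len) continue;
          int context = walks(r, cpos) - 1;
          double* v = &syn0[(size_t)context * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target; double label;
            if (neg == 0) { target = center; label = 1.0; }
            else {
              double rr = unif(rng) * tot;
              target = (int)(std::lower_bound(cum.begin(), cum.end(), rr) -
                             cum.begin());
              if (target >= n_nodes) target = n_nodes - 1;
              if (target == center) continue;
              label = 0.0;
            }
            double* u = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int kk = 0; kk < dim; ++kk) dot += v[kk] * u[kk];
            double pred = 1.0 / (1.0 + std::exp(-dot));
            double g = (label - pred) * lr;
            for (int kk = 0; kk < dim; ++kk) {
              grad[kk] += g * u[kk];
              u[kk] += g * v[kk];
            }
          }
          for (int kk = 0; kk < dim; ++kk) v[kk] += grad[kk];
        }
      }
    }
  }
  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int kk = 0; kk < dim; ++kk)
      out(i, kk) = syn0[(size_t)i * dim + kk];
  return out;
}
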