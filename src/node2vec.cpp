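// Biased second-order random walks and skip-gram training with negative
// sampling. All randomness comes from R's RNG (unif_rand) so results are
// reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline bool has_edge(const std::vector<int> &sorted_nbrs, int x) {
  return std::binary_search(sorted_nbrs.begin(), sorted_nbrs.end(), x);
}

// [[Rcpp::export]]
IntegerMatrix cpp_node2vec_walks(List adj, double p, double q,
                                 int walk_length, int walks_per_node) {
  const int n = adj.size();
  std::vector<std::vector<int>> nbrs(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    nbrs[i].assign(v.begin(), v.end());
  }
  IntegerMatrix walks(n * walks_per_node, walk_length);
  std::fill(walks.begin(), walks.end(), -1);
  std::vector<double> w;
  int row = 0;
  for (int r = 0; r < walks_per_node; ++r) {
    for (int s = 0; s < n; ++s, ++row) {
      int prev = -1, cur = s;
      walks(row, 0) = cur;
      for (int step = 1; step < walk_length; ++step) {
        const std::vector<int> &nb = nbrs[cur];
        if (nb.empty()) break;
        int nxt;
        if (prev < 0 || (p == 1.0 && q == 1.0)) {
          nxt = nb[(int)(unif_rand() * nb.size()) % nb.size()];
        } else {
          w.resize(nb.size());
          double tot = 0.0;
          for (size_t k = 0; k < nb.size(); ++k) {
            double wk;
            if (nb[k] == prev)
              wk = 1.0 / p;
            else if (has_edge(nbrs[prev], nb[k]))
              wk = 1.0;
            else
              wk = 1.0 / q;
            w[k] = wk;
            tot += wk;
          }
          double u = unif_rand() * tot, acc = 0.0;
          nxt = nb.back();
          for (size_t k = 0; k < nb.size(); ++k) {
            acc += w[k];
            if (u <= acc) { nxt = nb[k]; break; }
          }
        }
        walks(row, step) = nxt;
        prev = cur;
        cur = nxt;
      }
    }
  }
  return walks;
}

// [[Rcpp::export]]
NumericMatrix cpp_skipgram_train(IntegerMatrix walks, int n_nodes, int dim,
                                 int window, int n_negative, double lr,
                                 int epochs) {
  // unigram^0.75 negative-sampling table
  std::vector<double> cnt(n_nodes, 0.0);
  const int n_walks = walks.nrow(), wl = walks.ncol();
  for (int i = 0; i < n_walks; ++i)
    for (int j = 0; j < wl; ++j)
      if (walks(i, j) >= 0) cnt[walks(i, j)] += 1.0;
  const int table_size = 100000;
  std::vector<int> table(table_size);
  {
    double tot = 0.0;
    for (int v = 0; v < n_nodes; ++v) tot += std::pow(cnt[v], 0.75);
    if (tot <= 0.0) tot = 1.0;
    int v = 0;
    double cum = std::pow(cnt[0], 0.75) / tot;
    for (int t = 0; t < table_size; ++t) {
      table[t] = v;
      if ((double)(t + 1) / table_size > cum && v < n_nodes - 1) {
        ++v;
        cum += std::pow(cnt[v], 0.75) / tot;
      }
    }
  }
  // init: in-vectors uniform(-0.5,0.5)/dim, out-vectors zero
  std::vector<double> emb((size_t)n_nodes * dim), ctx((size_t)n_nodes * dim, 0.0);
  for (size_t i = 0; i < emb.size(); ++i)
    emb[i] = (unif_rand() - 0.5) / dim;
  std::vector<double> grad(dim);
  // count usable centers for the lr schedule
  long total_centers = 0;
  for (int i = 0; i < n_walks; ++i)
    for (int j = 0; j < wl; ++j)
      if (walks(i, j) >= 0) ++total_centers;
  total_centers *= epochs;
  long seen = 0;
  const double lr_min = lr * 1e-4;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < n_walks; ++i) {
      for (int j = 0; j < wl; ++j) {
        int center = walks(i, j);
        if (center < 0) break;
        double alpha = lr * (1.0 - (double)seen / (double)(total_centers + 1));
        if (alpha < lr_min) alpha = lr_min;
        ++seen;
        int b = (int)(unif_rand() * window) % window;  // shrunken window
        for (int k = j - window + b; k <= j + window - b; ++k) {
          if (k == j || k < 0 || k >= wl) continue;
          int tgt = walks(i, k);
          if (tgt < 0) continue;
          double *vc = &emb[(size_t)center * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= n_negative; ++neg) {
            int out;
            double label;
            if (neg == 0) {
              out = tgt;
              label = 1.0;
            } else {
              out = table[(int)(unif_rand() * table_size) % table_size];
              if (out == tgt) continue;
              label = 0.0;
            }
            double *vo = &ctx[(size_t)out * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += vc[d] * vo[d];
            double pred = 1.0 / (1.0 + std::exp(-dot));
            double g = (label - pred) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * vo[d];
              vo[d] += g * vc[d];
            }
          }
          for (int d = 0; d < dim; ++d) vc[d] += grad[d];
        }
      }
    }
  }
  NumericMatrix out(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v)
    for (int d = 0; d < dim; ++d) out(v, d) = emb[(size_t)v * dim + d];
  return out;
}
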