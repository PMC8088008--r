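// Minimal regression random forest: bootstrap aggregation of CART trees
// with per-node random feature subsampling (mtry) and variance-reduction
// splits. Exists to back Boruta-style feature selection; importance is
// the total in-sample SSE decrease attributed to each feature, averaged
// over trees. Deterministic given `seed` (own RNG, independent of R's).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(unif() * n) % n; }
};

struct Node {
  int feature = -1;      // -1: leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;
};

struct Tree {
  std::vector<Node> nodes;

  double predict_row(const NumericMatrix& X, int row) const {
    int cur = 0;
    while (nodes[cur].feature >= 0) {
      cur = (X(row, nodes[cur].feature) <= nodes[cur].threshold)
              ? nodes[cur].left : nodes[cur].right;
    }
    return nodes[cur].value;
  }
};

struct Builder {
  const NumericMatrix& X;
  const NumericVector& y;
  int mtry, min_node;
  XorShift& rng;
  std::vector<double>& importance;
  Tree tree;
  std::vector<int> feat_pool;

  Builder(const NumericMatrix& X_, const NumericVector& y_, int mtry_,
          int min_node_, XorShift& rng_, std::vector<double>& imp)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), rng(rng_),
        importance(imp), feat_pool(X_.ncol()) {
    for (int j = 0; j < X_.ncol(); ++j) feat_pool[j] = j;
  }

  int build(std::vector<int>& idx) {
    int id = static_cast<int>(tree.nodes.size());
    tree.nodes.push_back(Node());
    const int n = static_cast<int>(idx.size());
    double sum = 0.0, sum2 = 0.0;
    for (int i : idx) { sum += y[i]; sum2 += y[i] * y[i]; }
    const double node_sse = sum2 - sum * sum / n;
    tree.nodes[id].value = sum / n;
    if (n < 2 * min_node || node_sse <= 1e-12) return id;

    // partial Fisher-Yates: first mtry entries of feat_pool are the draw
    const int p = X.ncol();
    for (int j = 0; j < mtry; ++j) {
      int k = j + rng.below(p - j);
      std::swap(feat_pool[j], feat_pool[k]);
    }

    int best_feat = -1, best_pos = -1;
    double best_gain = 0.0, best_thr = 0.0;
    std::vector<std::pair<double, double>> xy(n);
    for (int j = 0; j < mtry; ++j) {
      const int f = feat_pool[j];
      for (int i = 0; i < n; ++i) xy[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(xy.begin(), xy.end());
      double lsum = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        lsum += xy[i].second;
        if (i + 1 < min_node || n - i - 1 < min_node) continue;
        if (xy[i].first == xy[i + 1].first) continue;
        const int nl = i + 1, nr = n - nl;
        const double rsum = sum - lsum;
        const double gain = lsum * lsum / nl + rsum * rsum / nr
                            - sum * sum / n;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = f;
          best_pos = i;
          best_thr = 0.5 * (xy[i].first + xy[i + 1].first);
        }
      }
    }
    if (best_feat < 0) return id;

    importance[best_feat] += best_gain;
    std::vector<int> left_idx, right_idx;
    left_idx.reserve(best_pos + 1);
    right_idx.reserve(n - best_pos - 1);
    for (int i : idx) {
      if (X(i, best_feat) <= best_thr) left_idx.push_back(i);
      else right_idx.push_back(i);
    }
    // degenerate partition guard (ties at the threshold)
    if (left_idx.empty() || right_idx.empty()) return id;
    tree.nodes[id].feature = best_feat;
    tree.nodes[id].threshold = best_thr;
    const int l = build(left_idx);
    const int r = build(right_idx);
    tree.nodes[id].left = l;
    tree.nodes[id].right = r;
    return id;
  }
};

} // namespace

namespace {

// tree prediction with one feature's value overridden (for OOB
// permutation importance)
double predict_row_swap(const Tree& tree, const NumericMatrix& X, int row,
                        int swap_feature, double swap_value) {
  int cur = 0;
  while (tree.nodes[cur].feature >= 0) {
    const Node& nd = tree.nodes[cur];
    const double v = (nd.feature == swap_feature)
                       ? swap_value : X(row, nd.feature);
    cur = (v <= nd.threshold) ? nd.left : nd.right;
  }
  return tree.nodes[cur].value;
}

} // namespace

// importance_type: 0 = in-sample variance reduction (total SSE decrease
// attributed to each splitting feature), 1 = out-of-bag permutation
// importance (mean increase in OOB MSE when the feature is permuted
// among the OOB rows). Permutation importance is the Boruta-grade
// measure: in-sample gain systematically rewards chance correlations.
// [[Rcpp::export(name = ".rf_regression_cpp")]]
List rf_regression_cpp(NumericMatrix X, NumericVector y, int num_trees,
                       int mtry, int min_node, double seed,
                       int importance_type) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) != nrow(X)");
  if (n < 2 * min_node) stop("fewer rows than the minimum node size allows");
  if (mtry < 1 || mtry > p) stop("mtry out of range");

  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  std::vector<double> importance(p, 0.0);
  std::vector<double> gain_importance(p, 0.0);
  std::vector<double> oob_sum(n, 0.0);
  std::vector<int> oob_cnt(n, 0);
  std::vector<int> in_bag(n);
  std::vector<int> idx, oob_idx, perm;
  idx.reserve(n);

  for (int t = 0; t < num_trees; ++t) {
    std::fill(in_bag.begin(), in_bag.end(), 0);
    idx.clear();
    for (int i = 0; i < n; ++i) {
      int r = rng.below(n);
      idx.push_back(r);
      in_bag[r] = 1;
    }
    Builder b(X, y, mtry, min_node, rng, gain_importance);
    b.build(idx);

    oob_idx.clear();
    for (int i = 0; i < n; ++i) if (!in_bag[i]) oob_idx.push_back(i);
    const int m = static_cast<int>(oob_idx.size());
    if (m == 0) continue;

    std::vector<double> base_pred(m);
    double base_sse = 0.0;
    for (int k = 0; k < m; ++k) {
      base_pred[k] = b.tree.predict_row(X, oob_idx[k]);
      const double e = base_pred[k] - y[oob_idx[k]];
      base_sse += e * e;
      oob_sum[oob_idx[k]] += base_pred[k];
      oob_cnt[oob_idx[k]] += 1;
    }

    if (importance_type == 1) {
      perm.resize(m);
      for (int f = 0; f < p; ++f) {
        for (int k = 0; k < m; ++k) perm[k] = k;
        for (int k = m - 1; k > 0; --k) {
          std::swap(perm[k], perm[rng.below(k + 1)]);
        }
        double sse = 0.0;
        for (int k = 0; k < m; ++k) {
          const double v = X(oob_idx[perm[k]], f);
          const double e =
            predict_row_swap(b.tree, X, oob_idx[k], f, v) - y[oob_idx[k]];
          sse += e * e;
        }
        importance[f] += (sse - base_sse) / m;
      }
    }
  }

  NumericVector imp(p), oob(n);
  for (int j = 0; j < p; ++j) {
    imp[j] = (importance_type == 1 ? importance[j] : gain_importance[j])
             / num_trees;
  }
  for (int i = 0; i < n; ++i) {
    oob[i] = oob_cnt[i] > 0 ? oob_sum[i] / oob_cnt[i] : NA_REAL;
  }
  return List::create(_["importance"] = imp, _["oob_prediction"] = oob);
}
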