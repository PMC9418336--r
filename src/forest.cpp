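// Compact CART random forest (classification, class probabilities).
// Written in-package because no random-forest implementation is available
// among the package's allowed dependencies. Deterministic given `seed`
// (own splitmix64/xorshift RNG, independent of R's RNG state).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct RNG {
  uint64_t s0, s1;
  explicit RNG(uint64_t seed) {
    // splitmix64 to initialise xorshift128+ state
    auto sm = [&seed]() {
      uint64_t z = (seed += 0x9E3779B97F4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      return z ^ (z >> 31);
    };
    s0 = sm(); s1 = sm();
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform integer in [0, n)
  int randint(int n) { return (int)(next() % (uint64_t)n); }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

struct Node {
  int feat = -1;          // -1 = leaf
  double thr = 0.0;
  int left = -1, right = -1;
  std::vector<double> prob; // leaf class distribution
};

struct Tree {
  std::vector<Node> nodes;
};

struct GrowCtx {
  const NumericMatrix& X;
  const IntegerVector& y;
  int k, mtry, min_split, max_depth;
  RNG& rng;
  std::vector<double>& importance;
};

double gini_total(const std::vector<int>& cnt, int n) {
  if (n == 0) return 0.0;
  double s = 0.0;
  for (int c : cnt) s += (double)c * c;
  return (double)n - s / n;
}

int grow_node(GrowCtx& ctx, Tree& tree, std::vector<int>& idx, int depth) {
  int n = (int)idx.size();
  std::vector<int> cnt(ctx.k, 0);
  for (int i : idx) cnt[ctx.y[i]]++;
  int maxc = *std::max_element(cnt.begin(), cnt.end());

  int node_id = (int)tree.nodes.size();
  tree.nodes.emplace_back();

  auto make_leaf = [&]() {
    Node& nd = tree.nodes[node_id];
    nd.feat = -1;
    nd.prob.resize(ctx.k);
    for (int c = 0; c < ctx.k; ++c) nd.prob[c] = (double)cnt[c] / n;
    return node_id;
  };

  if (maxc == n || n < ctx.min_split || depth >= ctx.max_depth) {
    return make_leaf();
  }

  int p = ctx.X.ncol();
  // sample mtry distinct features (partial Fisher-Yates)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = std::min(ctx.mtry, p);
  for (int j = 0; j < m; ++j) {
    int r = j + ctx.rng.randint(p - j);
    std::swap(feats[j], feats[r]);
  }

  double parent_imp = gini_total(cnt, n);
  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double,int> > vals(n);
  std::vector<int> cl(ctx.k), cr(ctx.k);
  for (int j = 0; j < m; ++j) {
    int f = feats[j];
    for (int i = 0; i < n; ++i) vals[i] = std::make_pair(ctx.X(idx[i], f), ctx.y[idx[i]]);
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    std::fill(cl.begin(), cl.end(), 0);
    cr = cnt;
    double sl = 0.0, sr = 0.0;
    for (int c = 0; c < ctx.k; ++c) sr += (double)cnt[c] * cnt[c];
    for (int i = 1; i < n; ++i) {
      int c = vals[i - 1].second;
      sl += 2.0 * cl[c] + 1.0; cl[c]++;
      sr -= 2.0 * cr[c] - 1.0; cr[c]--;
      if (vals[i].first > vals[i - 1].first) {
        double imp = (i - sl / i) + ((n - i) - sr / (n - i));
        double gain = parent_imp - imp;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i - 1].first);
        }
      }
    }
  }

  if (best_f < 0) return make_leaf();

  std::vector<int> lidx, ridx;
  lidx.reserve(n); ridx.reserve(n);
  for (int i : idx) {
    if (ctx.X(i, best_f) <= best_thr) lidx.push_back(i); else ridx.push_back(i);
  }
  if (lidx.empty() || ridx.empty()) return make_leaf();

  ctx.importance[best_f] += best_gain;
  {
    Node& nd = tree.nodes[node_id];
    nd.feat = best_f;
    nd.thr = best_thr;
  }
  int l = grow_node(ctx, tree, lidx, depth + 1);
  int r = grow_node(ctx, tree, ridx, depth + 1);
  tree.nodes[node_id].left = l;
  tree.nodes[node_id].right = r;
  return node_id;
}

List tree_to_list(const Tree& tree, int k) {
  int nn = (int)tree.nodes.size();
  IntegerVector feat(nn), left(nn), right(nn);
  NumericVector thr(nn);
  NumericMatrix prob(nn, k);
  for (int i = 0; i < nn; ++i) {
    const Node& nd = tree.nodes[i];
    feat[i] = nd.feat; thr[i] = nd.thr;
    left[i] = nd.left; right[i] = nd.right;
    if (nd.feat < 0) for (int c = 0; c < k; ++c) prob(i, c) = nd.prob[c];
  }
  return List::create(_["feat"] = feat, _["thr"] = thr,
                      _["left"] = left, _["right"] = right,
                      _["prob"] = prob);
}

} // namespace

// [[Rcpp::export]]
List sf_grow_forest(NumericMatrix X, IntegerVector y, int n_class,
                    int n_trees, int mtry, int min_split, int max_depth,
                    double sample_frac, double seed) {
  int n = X.nrow();
  RNG rng((uint64_t)seed + 0x5DEECE66DULL);
  std::vector<double> importance(X.ncol(), 0.0);
  List trees(n_trees);
  int nboot = std::max(1, (int)std::lround(sample_frac * n));
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(nboot);
    for (int i = 0; i < nboot; ++i) idx[i] = rng.randint(n); // with replacement
    Tree tree;
    GrowCtx ctx{X, y, n_class, mtry, min_split, max_depth, rng, importance};
    grow_node(ctx, tree, idx, 0);
    trees[t] = tree_to_list(tree, n_class);
  }
  return List::create(_["trees"] = trees,
                      _["importance"] = NumericVector(importance.begin(), importance.end()));
}

// [[Rcpp::export]]
NumericMatrix sf_predict_forest(List trees, NumericMatrix X, int n_class) {
  int n = X.nrow();
  int nt = trees.size();
  NumericMatrix out(n, n_class);
  for (int t = 0; t < nt; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feat"];
    NumericVector thr = tr["thr"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericMatrix prob = tr["prob"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0) {
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      }
      for (int c = 0; c < n_class; ++c) out(i, c) += prob(node, c);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < n_class; ++c) out(i, c) /= nt;
  return out;
}
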