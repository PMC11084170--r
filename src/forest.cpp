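// Regression random forest: CART trees with variance-reduction splits,
// bootstrap resampling and per-node feature subsampling. Deterministic for
// a given seed (std::mt19937, independent of R's RNG).

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct TreeNode {
  int feature;      // -1 for leaf
  double threshold; // goes left if x <= threshold
  int left, right;
  double value;     // leaf mean
};

struct BuildCtx {
  const NumericMatrix& X;
  const NumericVector& y;
  int mtry, max_depth, min_leaf;
  std::mt19937& rng;
  std::vector<TreeNode>& nodes;
  std::vector<double>& importance;
  BuildCtx(const NumericMatrix& X_, const NumericVector& y_, int mtry_,
           int max_depth_, int min_leaf_, std::mt19937& rng_,
           std::vector<TreeNode>& nodes_, std::vector<double>& imp_)
      : X(X_), y(y_), mtry(mtry_), max_depth(max_depth_), min_leaf(min_leaf_),
        rng(rng_), nodes(nodes_), importance(imp_) {}
};

static int build_node(BuildCtx& ctx, std::vector<int>& idx, int depth) {
  const int n = (int)idx.size();
  double sum = 0.0, sum2 = 0.0;
  for (int i : idx) { sum += ctx.y[i]; sum2 += ctx.y[i] * ctx.y[i]; }
  const double mean = sum / n;
  const double sse = sum2 - sum * sum / n;

  TreeNode node; node.feature = -1; node.threshold = 0.0;
  node.left = node.right = -1; node.value = mean;

  bool can_split = n >= 2 * ctx.min_leaf && n >= 2 && sse > 1e-12 &&
                   (ctx.max_depth < 0 || depth < ctx.max_depth);
  int best_f = -1;
  double best_gain = 1e-12, best_thr = 0.0;

  if (can_split) {
    const int p = ctx.X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    // partial Fisher-Yates: first mtry entries are the candidate features
    for (int j = 0; j < ctx.mtry && j < p; ++j) {
      std::uniform_int_distribution<int> d(j, p - 1);
      std::swap(feats[j], feats[d(ctx.rng)]);
    }
    std::vector<std::pair<double, double>> xy(n);
    for (int fj = 0; fj < ctx.mtry && fj < p; ++fj) {
      const int f = feats[fj];
      const double* col = &ctx.X(0, f);
      for (int k = 0; k < n; ++k) xy[k] = {col[idx[k]], ctx.y[idx[k]]};
      std::sort(xy.begin(), xy.end());
      if (xy.front().first >= xy.back().first) continue; // constant feature
      double lsum = 0.0, lsum2 = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        const double yv = xy[k].second;
        lsum += yv; lsum2 += yv * yv;
        const int nl = k + 1, nr = n - nl;
        if (nl < ctx.min_leaf || nr < ctx.min_leaf) continue;
        const double xk = xy[k].first, xk1 = xy[k + 1].first;
        if (xk1 <= xk) continue; // no boundary between equal values
        const double rsum = sum - lsum, rsum2 = sum2 - lsum2;
        const double child_sse = (lsum2 - lsum * lsum / nl) +
                                 (rsum2 - rsum * rsum / nr);
        const double gain = sse - child_sse;
        if (gain > best_gain) {
          best_gain = gain; best_f = f;
          best_thr = xk + (xk1 - xk) / 2.0;
        }
      }
    }
  }

  const int me = (int)ctx.nodes.size();
  ctx.nodes.push_back(node);
  if (best_f >= 0) {
    ctx.importance[best_f] += best_gain;
    std::vector<int> lidx, ridx;
    lidx.reserve(n); ridx.reserve(n);
    const double* col = &ctx.X(0, best_f);
    for (int k = 0; k < n; ++k) {
      if (col[idx[k]] <= best_thr) lidx.push_back(idx[k]);
      else ridx.push_back(idx[k]);
    }
    ctx.nodes[me].feature = best_f;
    ctx.nodes[me].threshold = best_thr;
    int l = build_node(ctx, lidx, depth + 1);
    int r = build_node(ctx, ridx, depth + 1);
    ctx.nodes[me].left = l;
    ctx.nodes[me].right = r;
  }
  return me;
}

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                int max_depth, int min_leaf, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least 2 training samples");
  List trees(n_trees);
  std::vector<double> importance(p, 0.0);
  for (int t = 0; t < n_trees; ++t) {
    std::mt19937 rng((unsigned)(seed) + 7919u * (unsigned)t);
    std::uniform_int_distribution<int> boot(0, n - 1);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    std::vector<TreeNode> nodes;
    nodes.reserve(2 * n);
    BuildCtx ctx(X, y, mtry, max_depth, min_leaf, rng, nodes, importance);
    build_node(ctx, idx, 0);
    const int m = (int)nodes.size();
    IntegerVector feature(m), left(m), right(m);
    NumericVector threshold(m), value(m);
    for (int k = 0; k < m; ++k) {
      feature[k] = nodes[k].feature; threshold[k] = nodes[k].threshold;
      left[k] = nodes[k].left; right[k] = nodes[k].right;
      value[k] = nodes[k].value;
    }
    trees[t] = List::create(_["feature"] = feature, _["threshold"] = threshold,
                            _["left"] = left, _["right"] = right,
                            _["value"] = value);
  }
  return List::create(_["trees"] = trees,
                      _["importance"] = NumericVector(importance.begin(),
                                                      importance.end()));
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X, int n_use) {
  const int n = X.nrow();
  const int T = (n_use > 0 && n_use <= trees.size()) ? n_use : trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
      }
      out[i] += value[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
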