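// Regression random forest used as the learner inside recursive feature
// elimination. CART variance-reduction splits, bootstrap resampling, mtry
// feature subsampling, impurity (SSE-decrease) importance. Uses R's RNG so
// results are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feature;     // -1 for leaf
  double threshold;
  int left, right; // node indices
  double value;    // mean of y in node (prediction for leaves)
};

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
  bool found = false;
};

// best SSE-decrease split over a random subset of mtry features
SplitResult best_split(const NumericMatrix& X, const NumericVector& y,
                       const std::vector<int>& idx,
                       std::vector<int>& feat_pool, int mtry) {
  const int n = static_cast<int>(idx.size());
  const int p = X.ncol();
  double sum = 0.0;
  for (int i : idx) sum += y[i];

  SplitResult best;
  // partial Fisher-Yates to draw mtry features without replacement
  for (int t = 0; t < mtry && t < p; ++t) {
    int j = t + static_cast<int>(unif_rand() * (p - t));
    if (j >= p) j = p - 1;
    std::swap(feat_pool[t], feat_pool[j]);
    const int f = feat_pool[t];

    // sort node samples by feature value
    std::vector<std::pair<double, double> > xy;
    xy.reserve(n);
    for (int i : idx) xy.push_back(std::make_pair(X(i, f), y[i]));
    std::sort(xy.begin(), xy.end());
    if (xy.front().first == xy.back().first) continue; // constant feature

    double sum_left = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      sum_left += xy[k].second;
      if (xy[k].first == xy[k + 1].first) continue;
      const int nl = k + 1, nr = n - nl;
      const double sum_right = sum - sum_left;
      const double gain = sum_left * sum_left / nl +
                          sum_right * sum_right / nr - sum * sum / n;
      if (!best.found || gain > best.gain) {
        best.found = true;
        best.gain = gain;
        best.feature = f;
        best.threshold = 0.5 * (xy[k].first + xy[k + 1].first);
      }
    }
  }
  return best;
}

void grow_tree(const NumericMatrix& X, const NumericVector& y,
               std::vector<int>& sample, int mtry, int min_node,
               std::vector<Node>& nodes, std::vector<double>& importance) {
  const int p = X.ncol();
  std::vector<int> feat_pool(p);
  for (int j = 0; j < p; ++j) feat_pool[j] = j;

  // stack of (node index, sample indices)
  struct Task { int node; std::vector<int> idx; };
  std::vector<Task> stack;
  nodes.clear();
  nodes.push_back(Node());
  {
    Task t; t.node = 0; t.idx = sample;
    stack.push_back(t);
  }
  while (!stack.empty()) {
    Task t = stack.back();
    stack.pop_back();
    const int n = static_cast<int>(t.idx.size());
    double sum = 0.0;
    for (int i : t.idx) sum += y[i];
    Node& nd = nodes[t.node];
    nd.feature = -1;
    nd.value = sum / n;
    if (n <= min_node) continue;
    bool pure = true;
    for (int i : t.idx) if (y[i] != y[t.idx[0]]) { pure = false; break; }
    if (pure) continue;

    SplitResult s = best_split(X, y, t.idx, feat_pool, mtry);
    if (!s.found || s.gain <= 0.0) continue;

    std::vector<int> left_idx, right_idx;
    for (int i : t.idx) {
      if (X(i, s.feature) <= s.threshold) left_idx.push_back(i);
      else right_idx.push_back(i);
    }
    if (left_idx.empty() || right_idx.empty()) continue;

    importance[s.feature] += s.gain;
    const int li = static_cast<int>(nodes.size());
    nodes.push_back(Node());
    const int ri = static_cast<int>(nodes.size());
    nodes.push_back(Node());
    nodes[t.node].feature = s.feature;
    nodes[t.node].threshold = s.threshold;
    nodes[t.node].left = li;
    nodes[t.node].right = ri;
    Task tl; tl.node = li; tl.idx = left_idx; stack.push_back(tl);
    Task tr; tr.node = ri; tr.idx = right_idx; stack.push_back(tr);
  }
}

} // namespace

// [[Rcpp::export]]
List rf_build(NumericMatrix X, NumericVector y, int ntree, int mtry,
              int min_node) {
  const int n = X.nrow();
  if (n < 2) stop("rf_build: need at least 2 observations");
  if (mtry < 1) mtry = 1;
  List trees(ntree);
  std::vector<double> importance(X.ncol(), 0.0);
  std::vector<Node> nodes;
  std::vector<int> sample(n);
  for (int b = 0; b < ntree; ++b) {
    for (int i = 0; i < n; ++i) {
      int k = static_cast<int>(unif_rand() * n);
      if (k >= n) k = n - 1;
      sample[i] = k;
    }
    grow_tree(X, y, sample, mtry, min_node, nodes, importance);
    NumericMatrix tm(static_cast<int>(nodes.size()), 5);
    for (size_t q = 0; q < nodes.size(); ++q) {
      tm(q, 0) = nodes[q].feature;
      tm(q, 1) = nodes[q].threshold;
      tm(q, 2) = nodes[q].left;
      tm(q, 3) = nodes[q].right;
      tm(q, 4) = nodes[q].value;
    }
    trees[b] = tm;
  }
  NumericVector imp(importance.begin(), importance.end());
  imp = imp / static_cast<double>(ntree);
  return List::create(Named("trees") = trees, Named("importance") = imp);
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int ntree = trees.size();
  NumericVector out(n, 0.0);
  for (int b = 0; b < ntree; ++b) {
    NumericMatrix tm = trees[b];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tm(node, 0) >= 0) {
        const int f = static_cast<int>(tm(node, 0));
        node = (X(i, f) <= tm(node, 1)) ? static_cast<int>(tm(node, 2))
                                        : static_cast<int>(tm(node, 3));
      }
      out[i] += tm(node, 4);
    }
  }
  return out / static_cast<double>(ntree);
}
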