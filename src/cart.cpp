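// Depth-limited exact CART regression trees with case weights: the base
// learner of the in-package boosting families. Greedy weighted-SSE
// splits over numeric features, midpoint thresholds, deterministic
// first-best tie-breaking.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct Node {
  int feature;      // -1 for a leaf
  double threshold; // go left if x <= threshold
  int left, right;
  double value;     // weighted mean of y in the node
};

static void grow(const NumericMatrix& X, const NumericVector& y,
                 const NumericVector& w, std::vector<int>& idx,
                 int depth, int max_depth, int min_split, int min_bucket,
                 std::vector<Node>& nodes, int node_id) {
  const int n = idx.size();
  const int p = X.ncol();

  double sw = 0.0, swy = 0.0;
  for (int k = 0; k < n; ++k) { sw += w[idx[k]]; swy += w[idx[k]] * y[idx[k]]; }
  nodes[node_id].value = (sw > 0.0) ? swy / sw : 0.0;
  nodes[node_id].feature = -1;

  if (depth >= max_depth || n < min_split || n < 2 * min_bucket || sw <= 0.0)
    return;

  bool constant = true;
  for (int k = 1; k < n && constant; ++k)
    if (y[idx[k]] != y[idx[0]]) constant = false;
  if (constant) return;

  const double parent_score = (swy * swy) / sw;
  double best_gain = 1e-12;
  int best_feature = -1;
  double best_threshold = 0.0;

  std::vector<std::pair<double, int> > ord(n);
  for (int j = 0; j < p; ++j) {
    for (int k = 0; k < n; ++k)
      ord[k] = std::make_pair(X(idx[k], j), idx[k]);
    std::sort(ord.begin(), ord.end());
    double swl = 0.0, swyl = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      const int i = ord[k].second;
      swl += w[i];
      swyl += w[i] * y[i];
      if (ord[k + 1].first <= ord[k].first) continue;  // no gap to split in
      const int nl = k + 1, nr = n - nl;
      if (nl < min_bucket || nr < min_bucket) continue;
      const double swr = sw - swl, swyr = swy - swyl;
      if (swl <= 0.0 || swr <= 0.0) continue;
      const double gain =
        (swyl * swyl) / swl + (swyr * swyr) / swr - parent_score;
      if (gain > best_gain) {
        best_gain = gain;
        best_feature = j;
        best_threshold = 0.5 * (ord[k].first + ord[k + 1].first);
      }
    }
  }
  if (best_feature < 0) return;

  std::vector<int> left_idx, right_idx;
  left_idx.reserve(n);
  right_idx.reserve(n);
  for (int k = 0; k < n; ++k) {
    if (X(idx[k], best_feature) <= best_threshold) left_idx.push_back(idx[k]);
    else right_idx.push_back(idx[k]);
  }
  if (left_idx.empty() || right_idx.empty()) return;

  const int li = nodes.size();
  nodes.push_back(Node());
  const int ri = nodes.size();
  nodes.push_back(Node());
  nodes[node_id].feature = best_feature;
  nodes[node_id].threshold = best_threshold;
  nodes[node_id].left = li;
  nodes[node_id].right = ri;
  grow(X, y, w, left_idx, depth + 1, max_depth, min_split, min_bucket,
       nodes, li);
  grow(X, y, w, right_idx, depth + 1, max_depth, min_split, min_bucket,
       nodes, ri);
}

// [[Rcpp::export(name = ".cart_fit")]]
List cart_fit(NumericMatrix X, NumericVector y, NumericVector w,
              int max_depth, int min_split, int min_bucket) {
  const int n = X.nrow();
  if (y.size() != n || w.size() != n)
    stop("X, y and w must have matching sizes");
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<Node> nodes;
  nodes.push_back(Node());
  grow(X, y, w, idx, 0, max_depth, min_split, min_bucket, nodes, 0);

  const int m = nodes.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m), value(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    value[i] = nodes[i].value;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value);
}

// [[Rcpp::export(name = ".cart_predict")]]
NumericVector cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"];
  IntegerVector right = tree["right"];
  NumericVector value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = value[node];
  }
  return out;
}
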