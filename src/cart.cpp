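// Minimal CART random forest: regression (variance split) and
// classification (Gini split). Backs the iterative imputation engine.
// Categorical predictors arrive one-hot encoded; only the response keeps
// its categorical identity (as 0-based integer classes).

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct TreeNode {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;  // node indices, -1 for leaf
  std::vector<double> value; // length 1 (regression) or nclass (class proportions)
};

struct SplitResult {
  int feature;
  double threshold;
  double score;   // criterion improvement; <= 0 means no usable split
  bool ok;
};

// Best split on one feature for regression: maximise sum_L^2/n_L + sum_R^2/n_R.
static void best_split_reg(const NumericMatrix &X, const std::vector<double> &y,
                           const std::vector<int> &idx, int feat,
                           SplitResult &best) {
  const int n = (int)idx.size();
  std::vector<std::pair<double, double>> v(n);
  for (int i = 0; i < n; ++i) v[i] = {X(idx[i], feat), y[i]};
  std::sort(v.begin(), v.end());
  if (v.front().first == v.back().first) return; // constant feature
  double total = 0.0;
  for (auto &p : v) total += p.second;
  double base = total * total / n;
  double cumsum = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    cumsum += v[i].second;
    if (v[i].first == v[i + 1].first) continue;
    double nl = i + 1, nr = n - nl;
    double score = cumsum * cumsum / nl +
                   (total - cumsum) * (total - cumsum) / nr - base;
    if (score > best.score) {
      best.score = score;
      best.feature = feat;
      best.threshold = 0.5 * (v[i].first + v[i + 1].first);
      best.ok = true;
    }
  }
}

// Best split on one feature for classification: minimise weighted Gini.
static void best_split_cls(const NumericMatrix &X, const std::vector<int> &y,
                           const std::vector<int> &idx, int feat, int nclass,
                           SplitResult &best) {
  const int n = (int)idx.size();
  std::vector<std::pair<double, int>> v(n);
  for (int i = 0; i < n; ++i) v[i] = {X(idx[i], feat), y[i]};
  std::sort(v.begin(), v.end());
  if (v.front().first == v.back().first) return;
  std::vector<double> left(nclass, 0.0), tot(nclass, 0.0);
  for (auto &p : v) tot[p.second] += 1.0;
  double base = 0.0;
  for (int c = 0; c < nclass; ++c) base += tot[c] * tot[c];
  base /= n; // n * (1 - gini(parent)) up to constant
  for (int i = 0; i < n - 1; ++i) {
    left[v[i].second] += 1.0;
    if (v[i].first == v[i + 1].first) continue;
    double nl = i + 1, nr = n - nl;
    double sl = 0.0, sr = 0.0;
    for (int c = 0; c < nclass; ++c) {
      sl += left[c] * left[c];
      double r = tot[c] - left[c];
      sr += r * r;
    }
    double score = sl / nl + sr / nr - base;
    if (score > best.score) {
      best.score = score;
      best.feature = feat;
      best.threshold = 0.5 * (v[i].first + v[i + 1].first);
      best.ok = true;
    }
  }
}

static int build_node(const NumericMatrix &X, const std::vector<double> &yreg,
                      const std::vector<int> &ycls, bool classify, int nclass,
                      std::vector<int> idx, int depth, int mtry, int min_node,
                      int max_depth, std::mt19937 &rng,
                      std::vector<TreeNode> &nodes) {
  TreeNode node;
  node.feature = -1;
  node.left = node.right = -1;
  const int n = (int)idx.size();
  if (classify) {
    node.value.assign(nclass, 0.0);
    for (int i : idx) node.value[ycls[i]] += 1.0 / n;
  } else {
    double m = 0.0;
    for (int i : idx) m += yreg[i];
    node.value.assign(1, m / n);
  }

  bool pure = true;
  if (classify) {
    for (size_t i = 1; i < idx.size(); ++i)
      if (ycls[idx[i]] != ycls[idx[0]]) { pure = false; break; }
  } else {
    for (size_t i = 1; i < idx.size(); ++i)
      if (yreg[idx[i]] != yreg[idx[0]]) { pure = false; break; }
  }

  if (n >= 2 * min_node && depth < max_depth && !pure) {
    const int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    std::shuffle(feats.begin(), feats.end(), rng);
    SplitResult best{-1, 0.0, 1e-12, false};
    int tried = 0;
    for (int j = 0; j < p && tried < mtry; ++j) {
      if (classify) {
        std::vector<int> ysub;
        ysub.reserve(n);
        for (int i : idx) ysub.push_back(ycls[i]);
        best_split_cls(X, ysub, idx, feats[j], nclass, best);
      } else {
        std::vector<double> ysub;
        ysub.reserve(n);
        for (int i : idx) ysub.push_back(yreg[i]);
        best_split_reg(X, ysub, idx, feats[j], best);
      }
      ++tried;
    }
    if (best.ok) {
      std::vector<int> li, ri;
      for (int i : idx)
        (X(i, best.feature) <= best.threshold ? li : ri).push_back(i);
      if ((int)li.size() >= min_node && (int)ri.size() >= min_node) {
        node.feature = best.feature;
        node.threshold = best.threshold;
        int self = (int)nodes.size();
        nodes.push_back(node);
        int l = build_node(X, yreg, ycls, classify, nclass, li, depth + 1,
                           mtry, min_node, max_depth, rng, nodes);
        int r = build_node(X, yreg, ycls, classify, nclass, ri, depth + 1,
                           mtry, min_node, max_depth, rng, nodes);
        nodes[self].left = l;
        nodes[self].right = r;
        return self;
      }
    }
  }
  nodes.push_back(node);
  return (int)nodes.size() - 1;
}

static List tree_to_list(const std::vector<TreeNode> &nodes, int nclass) {
  const int n = (int)nodes.size();
  IntegerVector feature(n), left(n), right(n);
  NumericVector threshold(n);
  NumericMatrix value(n, nclass);
  for (int i = 0; i < n; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    for (int c = 0; c < (int)nodes[i].value.size(); ++c)
      value(i, c) = nodes[i].value[c];
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value);
}

// [[Rcpp::export(.cart_forest_fit)]]
List cart_forest_fit(NumericMatrix X, NumericVector y, bool classify,
                     int nclass, int ntree, int mtry, int min_node,
                     int max_depth, int seed) {
  const int n = X.nrow();
  std::vector<double> yreg(n);
  std::vector<int> ycls(n);
  if (classify) {
    for (int i = 0; i < n; ++i) ycls[i] = (int)y[i];
  } else {
    for (int i = 0; i < n; ++i) yreg[i] = y[i];
  }
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::mt19937 rng((unsigned)seed + 7919u * (unsigned)t);
    std::uniform_int_distribution<int> pick(0, n - 1);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = pick(rng);
    std::vector<TreeNode> nodes;
    nodes.reserve(2 * n);
    build_node(X, yreg, ycls, classify, nclass, idx, 0, mtry, min_node,
               max_depth, rng, nodes);
    trees[t] = tree_to_list(nodes, classify ? nclass : 1);
  }
  return trees;
}

// [[Rcpp::export(.cart_forest_predict)]]
NumericMatrix cart_forest_predict(List forest, NumericMatrix X, bool classify,
                                  int nclass) {
  const int n = X.nrow();
  const int nt = forest.size();
  const int k = classify ? nclass : 1;
  NumericMatrix out(n, k);
  for (int t = 0; t < nt; ++t) {
    List tree = forest[t];
    IntegerVector feature = tree["feature"], left = tree["left"],
                  right = tree["right"];
    NumericVector threshold = tree["threshold"];
    NumericMatrix value = tree["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      for (int c = 0; c < k; ++c) out(i, c) += value(node, c) / nt;
    }
  }
  return out;
}
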