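#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Random forest for binary classification: CART trees grown on bootstrap
// samples with Gini impurity and per-node random feature subsampling
// (mtry). Predicted probabilities are leaf class fractions averaged over
// trees, matching the convention of the common ML toolkits. Randomness
// comes from R's RNG (unif_rand), so set.seed() on the R side makes forests
// fully reproducible.

struct Tree {
  std::vector<int> feature, left, right;
  std::vector<double> threshold, prob;
};

static int rand_int(int n) { // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

class Grower {
public:
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, max_depth, min_split;
  Tree tree;
  std::vector<int> feat_pool;

  Grower(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
         int max_depth_, int min_split_)
    : X(X_), y(y_), mtry(mtry_), max_depth(max_depth_),
      min_split(min_split_) {
    feat_pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
  }

  int build(std::vector<int>& idx, int depth) {
    int node = tree.feature.size();
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    int n = idx.size(), pos = 0;
    for (int i : idx) pos += y[i];
    tree.prob.push_back((double)pos / n);
    bool pure = (pos == 0 || pos == n);
    if (pure || n < min_split || (max_depth > 0 && depth >= max_depth))
      return node;

    // sample mtry features without replacement (partial Fisher-Yates)
    for (int j = 0; j < mtry; ++j)
      std::swap(feat_pool[j], feat_pool[j + rand_int(feat_pool.size() - j)]);

    double best_imp = R_PosInf, best_thr = 0.0;
    int best_f = -1;
    std::vector<std::pair<double, int>> vals(n);
    for (int j = 0; j < mtry; ++j) {
      int f = feat_pool[j];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      int lp = 0; // positives to the left of the split point
      for (int i = 0; i < n - 1; ++i) {
        lp += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl, rp = pos - lp;
        double pl = (double)lp / nl, pr = (double)rp / nr;
        double imp = nl * 2.0 * pl * (1.0 - pl) + nr * 2.0 * pr * (1.0 - pr);
        if (imp < best_imp) {
          best_imp = imp;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return node; // no valid split among sampled features

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i);
      else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return node;
    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                     int max_depth, int min_split) {
  RNGScope scope;
  int n = X.nrow();
  List forest(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rand_int(n); // bootstrap
    Grower g(X, y, mtry, max_depth, min_split);
    g.build(idx, 0);
    forest[t] = List::create(
      _["feature"] = wrap(g.tree.feature),
      _["threshold"] = wrap(g.tree.threshold),
      _["left"] = wrap(g.tree.left),
      _["right"] = wrap(g.tree.right),
      _["prob"] = wrap(g.tree.prob));
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List forest, NumericMatrix X) {
  int n = X.nrow(), T = forest.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tr = forest[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
      right = tr["right"];
    NumericVector threshold = tr["threshold"], prob = tr["prob"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      }
      out[i] += prob[node];
    }
  }
  return out / (double)T;
}
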