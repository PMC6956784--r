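// Random-forest regression: CART trees with variance-reduction splits,
// bootstrap resampling and per-node feature subsampling (mtry).
// Self-contained RNG (mt19937) so fits are reproducible from a single seed
// independently of R's RNG state.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct TreeNodes {
  // feature < 0 marks a leaf; value holds the leaf mean
  std::vector<int> feature, left, right;
  std::vector<double> thresh, value;
  int add_node() {
    feature.push_back(-1); left.push_back(-1); right.push_back(-1);
    thresh.push_back(0.0); value.push_back(0.0);
    return static_cast<int>(feature.size()) - 1;
  }
};

struct SplitResult {
  int feature = -1;
  double thresh = 0.0;
  double decrease = 0.0;   // SSE decrease achieved by the split
  bool found = false;
};

// Best axis-aligned split over a random subset of `mtry` features.
SplitResult best_split(const NumericMatrix& X, const NumericVector& y,
                       const std::vector<int>& idx, int mtry,
                       std::mt19937& rng) {
  const int p = X.ncol();
  const int n = static_cast<int>(idx.size());
  SplitResult best;

  // node SSE before splitting
  double sum = 0.0, sq = 0.0;
  for (int i : idx) { sum += y[i]; sq += y[i] * y[i]; }
  const double node_sse = sq - sum * sum / n;
  if (node_sse <= 1e-12) return best;  // pure node

  // sample mtry distinct features (partial Fisher-Yates)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  const int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    std::uniform_int_distribution<int> d(j, p - 1);
    std::swap(feats[j], feats[d(rng)]);
  }

  std::vector<std::pair<double, double>> xy(n);
  for (int jj = 0; jj < m; ++jj) {
    const int f = feats[jj];
    for (int k = 0; k < n; ++k) xy[k] = {X(idx[k], f), y[idx[k]]};
    std::sort(xy.begin(), xy.end());
    if (xy.front().first == xy.back().first) continue;  // constant feature

    double lsum = 0.0, lsq = 0.0, rsum = sum, rsq = sq;
    for (int k = 0; k < n - 1; ++k) {
      const double yi = xy[k].second;
      lsum += yi; lsq += yi * yi; rsum -= yi; rsq -= yi * yi;
      if (xy[k].first == xy[k + 1].first) continue;  // no valid cut here
      const int nl = k + 1, nr = n - nl;
      const double child_sse = (lsq - lsum * lsum / nl) + (rsq - rsum * rsum / nr);
      const double dec = node_sse - child_sse;
      if (dec > best.decrease + 1e-12) {
        best.decrease = dec;
        best.feature = f;
        best.thresh = 0.5 * (xy[k].first + xy[k + 1].first);
        best.found = true;
      }
    }
  }
  return best;
}

void grow(TreeNodes& tree, int node, const NumericMatrix& X,
          const NumericVector& y, std::vector<int>& idx, int mtry,
          int min_node, std::mt19937& rng, std::vector<double>& importance) {
  const int n = static_cast<int>(idx.size());
  double mean = 0.0;
  for (int i : idx) mean += y[i];
  mean /= n;
  tree.value[node] = mean;
  if (n < std::max(2, min_node)) return;

  SplitResult s = best_split(X, y, idx, mtry, rng);
  if (!s.found) return;

  std::vector<int> lidx, ridx;
  lidx.reserve(n); ridx.reserve(n);
  for (int i : idx) (X(i, s.feature) <= s.thresh ? lidx : ridx).push_back(i);
  if (lidx.empty() || ridx.empty()) return;  // numeric degeneracy guard

  importance[s.feature] += s.decrease;
  tree.feature[node] = s.feature;
  tree.thresh[node] = s.thresh;
  const int l = tree.add_node(), r = tree.add_node();
  tree.left[node] = l; tree.right[node] = r;
  std::vector<int>().swap(idx);  // free before recursing
  grow(tree, l, X, y, lidx, mtry, min_node, rng, importance);
  grow(tree, r, X, y, ridx, mtry, min_node, rng, importance);
}

double predict_one(const List& tree, const NumericMatrix& X, int row) {
  const IntegerVector feature = tree["feature"], left = tree["left"],
                      right = tree["right"];
  const NumericVector thresh = tree["thresh"], value = tree["value"];
  int node = 0;
  while (feature[node] >= 0)
    node = (X(row, feature[node]) <= thresh[node]) ? left[node] : right[node];
  return value[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                int min_node, double sample_fraction, bool replace,
                int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least 2 rows to fit a forest");
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::vector<double> importance(p, 0.0);
  List trees(n_trees);
  const int n_samp = std::max(1, static_cast<int>(std::floor(sample_fraction * n)));

  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx;
    idx.reserve(n_samp);
    if (replace) {
      std::uniform_int_distribution<int> d(0, n - 1);
      for (int k = 0; k < n_samp; ++k) idx.push_back(d(rng));
    } else {
      std::vector<int> all(n);
      for (int i = 0; i < n; ++i) all[i] = i;
      for (int k = 0; k < n_samp; ++k) {
        std::uniform_int_distribution<int> d(k, n - 1);
        std::swap(all[k], all[d(rng)]);
      }
      idx.assign(all.begin(), all.begin() + n_samp);
    }
    TreeNodes tree;
    const int root = tree.add_node();
    grow(tree, root, X, y, idx, mtry, min_node, rng, importance);
    trees[t] = List::create(_["feature"] = wrap(tree.feature),
                            _["left"] = wrap(tree.left),
                            _["right"] = wrap(tree.right),
                            _["thresh"] = wrap(tree.thresh),
                            _["value"] = wrap(tree.value));
  }
  return List::create(_["trees"] = trees,
                      _["importance"] = wrap(importance),
                      _["n_trees"] = n_trees, _["mtry"] = mtry,
                      _["min_node"] = min_node);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  const List trees = forest["trees"];
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    const List tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_one(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
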