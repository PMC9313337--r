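// Compact CART random forest for binary classification with mean-decrease-
// Gini importance. Bootstrap per tree, mtry features per split, nodes grown
// to purity (or min_node). Uses R's RNG so results are reproducible under
// set.seed() on the R side.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;       // -1: leaf
  double threshold = 0.0; // go left if x <= threshold
  int left = -1, right = -1;
  double prob1 = 0.0;     // class-1 proportion in the node (leaf payload)
};

struct Tree {
  std::vector<Node> nodes;
};

double gini(double n1, double n) {
  if (n <= 0) return 0.0;
  double p = n1 / n;
  return 2.0 * p * (1.0 - p);
}

// Recursively grow a tree over sample indices idx.
int grow(std::vector<Node>& nodes, const NumericMatrix& X,
         const IntegerVector& y, std::vector<int>& idx, int lo, int hi,
         int mtry, int min_node, std::vector<double>& importance) {
  int me = (int)nodes.size();
  nodes.push_back(Node());
  int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  nodes[me].prob1 = n > 0 ? (double)n1 / n : 0.0;
  if (n < 2 * 1 || n <= min_node || n1 == 0 || n1 == n) return me;

  int p = X.ncol();
  // sample mtry features without replacement (partial Fisher-Yates)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int k = j + (int)(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(feats[j], feats[k]);
  }

  double parent_imp = gini((double)n1, (double)n) * n;
  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, int>> vals(n);
  for (int j = 0; j < m; ++j) {
    int f = feats[j];
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(X(idx[lo + i], f), y[idx[lo + i]]);
    std::sort(vals.begin(), vals.end());
    double left1 = 0, left = 0;
    for (int i = 0; i + 1 < n; ++i) {
      left1 += vals[i].second;
      left += 1;
      if (vals[i].first == vals[i + 1].first) continue;
      double right = n - left, right1 = n1 - left1;
      double child_imp = gini(left1, left) * left + gini(right1, right) * right;
      double gain = parent_imp - child_imp;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = (vals[i].first + vals[i + 1].first) / 2.0;
      }
    }
  }
  if (best_f < 0) return me;  // no informative split among sampled features

  importance[best_f] += best_gain;  // unnormalised Gini decrease

  // partition idx[lo, hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i) {
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  }
  if (mid == lo || mid == hi) return me;  // numeric degeneracy guard

  nodes[me].feature = best_f;
  nodes[me].threshold = best_thr;
  int l = grow(nodes, X, y, idx, lo, mid, mtry, min_node, importance);
  nodes[me].left = l;
  int r = grow(nodes, X, y, idx, mid, hi, mtry, min_node, importance);
  nodes[me].right = r;
  return me;
}

double predict_one(const Tree& tr, const NumericMatrix& X, int row) {
  int cur = 0;
  while (tr.nodes[cur].feature >= 0) {
    cur = X(row, tr.nodes[cur].feature) <= tr.nodes[cur].threshold
              ? tr.nodes[cur].left
              : tr.nodes[cur].right;
  }
  return tr.nodes[cur].prob1;
}

}  // namespace

// Fit a forest on (X, y) and return OOB class-1 probabilities, test-set
// probabilities (vote fractions) and mean-decrease-Gini importances.
// [[Rcpp::export]]
List rf_fit_predict(NumericMatrix X, IntegerVector y, NumericMatrix Xtest,
                    int ntree, int mtry, int min_node) {
  int n = X.nrow(), p = X.ncol(), ntest = Xtest.nrow();
  RNGScope scope;
  std::vector<double> importance(p, 0.0);
  NumericVector oob_votes(n), oob_count(n);
  NumericVector test_votes(ntest);
  std::vector<int> in_bag(n);

  for (int t = 0; t < ntree; ++t) {
    std::fill(in_bag.begin(), in_bag.end(), 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[i] = k;
      in_bag[k] = 1;
    }
    Tree tr;
    tr.nodes.reserve(2 * n);
    grow(tr.nodes, X, y, idx, 0, n, mtry, min_node, importance);
    for (int i = 0; i < n; ++i) {
      if (!in_bag[i]) {
        oob_votes[i] += predict_one(tr, X, i) >= 0.5 ? 1.0 : 0.0;
        oob_count[i] += 1.0;
      }
    }
    for (int i = 0; i < ntest; ++i) {
      test_votes[i] += predict_one(tr, Xtest, i) >= 0.5 ? 1.0 : 0.0;
    }
  }

  NumericVector oob_prob(n);
  for (int i = 0; i < n; ++i) {
    oob_prob[i] = oob_count[i] > 0 ? oob_votes[i] / oob_count[i] : NA_REAL;
  }
  NumericVector test_prob(ntest);
  for (int i = 0; i < ntest; ++i) test_prob[i] = test_votes[i] / ntree;
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / ntree;
  return List::create(_["oob_prob"] = oob_prob, _["test_prob"] = test_prob,
                      _["importance"] = imp);
}
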