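// CART growth with Gini impurity and best-first split selection.
// Thresholds sit at midpoints of consecutive distinct sorted values;
// equal-gain ties resolve to the lowest feature index, then the lowest
// threshold (guaranteed by ascending scan order with strict improvement).
// Growth is deterministic; all randomness (bootstrap resampling) lives in R.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct SplitChoice {
  double gain;      // total impurity decrease, n_parent * g_p - (n_l g_l + n_r g_r)
  int feature;      // 0-based, -1 if no valid split
  double threshold;
};

// sum over classes of counts^2, used in n * gini = n - sum c^2 / n
static inline double impurity_n(const std::vector<double>& cnt, double n) {
  if (n <= 0) return 0.0;
  double s2 = 0.0;
  for (double c : cnt) s2 += c * c;
  return n - s2 / n;
}

static SplitChoice best_split(const NumericMatrix& X, const IntegerVector& y,
                              int n_classes, const std::vector<int>& idx) {
  SplitChoice best;
  best.gain = 0.0; best.feature = -1; best.threshold = 0.0;
  const int n = (int)idx.size();
  if (n < 2) return best;

  std::vector<double> parent(n_classes, 0.0);
  for (int i : idx) parent[y[i]] += 1.0;
  double imp_parent = impurity_n(parent, n);
  if (imp_parent <= 0.0) return best;  // pure node

  std::vector<int> ord(idx);
  std::vector<double> left(n_classes), right(n_classes);
  for (int j = 0; j < X.ncol(); ++j) {
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      double va = X(a, j), vb = X(b, j);
      if (va != vb) return va < vb;
      return a < b;
    });
    std::fill(left.begin(), left.end(), 0.0);
    right = parent;
    for (int r = 0; r < n - 1; ++r) {
      int cls = y[ord[r]];
      left[cls] += 1.0; right[cls] -= 1.0;
      double v = X(ord[r], j), vnext = X(ord[r + 1], j);
      if (v == vnext) continue;  // not a boundary between distinct values
      double nl = r + 1, nr = n - r - 1;
      double gain = imp_parent - impurity_n(left, nl) - impurity_n(right, nr);
      if (gain > best.gain) {
        best.gain = gain;
        best.feature = j;
        best.threshold = 0.5 * (v + vnext);
      }
    }
  }
  return best;
}

// [[Rcpp::export(name = ".cart_grow")]]
List cart_grow(NumericMatrix X, IntegerVector y, int n_classes, int max_splits) {
  const int n = X.nrow();
  if (n < 1) stop("cannot grow a tree on an empty sample");

  std::vector<int> feature, left, right;
  std::vector<double> threshold;
  std::vector<std::vector<double>> dist;  // class counts per node

  std::vector<std::vector<int>> node_idx;   // sample indices per open node
  struct Open { int node; SplitChoice sp; };
  std::vector<Open> open;

  auto new_node = [&](const std::vector<int>& idx) {
    int id = (int)feature.size();
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    std::vector<double> cnt(n_classes, 0.0);
    for (int i : idx) cnt[y[i]] += 1.0;
    dist.push_back(cnt);
    node_idx.push_back(idx);
    Open o; o.node = id; o.sp = best_split(X, y, n_classes, idx);
    if (o.sp.feature >= 0) open.push_back(o);
    return id;
  };

  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  new_node(all);

  int splits = 0;
  while (splits < max_splits && !open.empty()) {
    // best-first: maximum gain, ties to the earliest-created node
    size_t pick = 0;
    for (size_t k = 1; k < open.size(); ++k) {
      if (open[k].sp.gain > open[pick].sp.gain ||
          (open[k].sp.gain == open[pick].sp.gain &&
           open[k].node < open[pick].node)) pick = k;
    }
    Open o = open[pick];
    open.erase(open.begin() + pick);

    std::vector<int> li, ri;
    for (int i : node_idx[o.node]) {
      if (X(i, o.sp.feature) <= o.sp.threshold) li.push_back(i);
      else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) continue;  // defensive; cannot happen
    feature[o.node] = o.sp.feature;
    threshold[o.node] = o.sp.threshold;
    int l = new_node(li), r = new_node(ri);
    left[o.node] = l;
    right[o.node] = r;
    node_idx[o.node].clear();
    ++splits;
  }

  int nn = (int)feature.size();
  NumericMatrix probs(nn, n_classes);
  for (int i = 0; i < nn; ++i) {
    double tot = 0.0;
    for (double c : dist[i]) tot += c;
    for (int k = 0; k < n_classes; ++k)
      probs(i, k) = tot > 0 ? dist[i][k] / tot : 0.0;
  }
  return List::create(_["feature"] = wrap(feature),
                      _["threshold"] = wrap(threshold),
                      _["left"] = wrap(left),
                      _["right"] = wrap(right),
                      _["probs"] = probs,
                      _["n_splits"] = splits);
}

// [[Rcpp::export(name = ".cart_predict")]]
NumericMatrix cart_predict(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericMatrix probs = tree["probs"];
  const int n = X.nrow(), nc = probs.ncol();
  NumericMatrix out(n, nc);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    }
    for (int k = 0; k < nc; ++k) out(i, k) = probs(node, k);
  }
  return out;
}
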