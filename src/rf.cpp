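#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Classification random forest: Gini CART trees on bootstrap samples with
// mtry feature subsampling. Uses R's RNG so that set.seed() on the R side
// makes growth fully reproducible. Ties in leaf majority vote go to the
// lowest class id.

namespace {

struct TreeBuf {
  std::vector<int> feat;      // split feature (0-based), -1 for leaf
  std::vector<double> thr;    // split threshold (x <= thr goes left)
  std::vector<int> left, right, pred;
};

int grow_node(const NumericMatrix& X, const IntegerVector& y, int K,
              std::vector<int>& idx, int lo, int hi, int mtry, int min_node,
              std::vector<int>& fpool, TreeBuf& T) {
  const int n = hi - lo;
  std::vector<int> cnt(K, 0);
  for (int i = lo; i < hi; ++i) cnt[y[idx[i]]]++;
  int maj = 0;
  for (int k = 1; k < K; ++k)
    if (cnt[k] > cnt[maj]) maj = k;
  const int node = (int)T.feat.size();
  T.feat.push_back(-1);
  T.thr.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.pred.push_back(maj);
  if (cnt[maj] == n || n < 2 * min_node || n < 2) return node;

  const int p = X.ncol();
  const int m = std::min(mtry, p);
  // parent and child purity compared through sum_k count_k^2 / size
  double base = 0.0;
  for (int k = 0; k < K; ++k) base += (double)cnt[k] * cnt[k];
  base /= n;

  double best_score = base;
  int best_f = -1;
  double best_thr = 0.0;
  std::vector<int> ord(n), lc(K);
  for (int j = 0; j < p; ++j) fpool[j] = j;
  for (int t = 0; t < m; ++t) {
    int r = t + (int)(unif_rand() * (p - t));
    if (r >= p) r = p - 1;
    std::swap(fpool[t], fpool[r]);
    const int f = fpool[t];
    std::copy(idx.begin() + lo, idx.begin() + hi, ord.begin());
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return X(a, f) < X(b, f); });
    std::fill(lc.begin(), lc.end(), 0);
    double suml = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      const int c = y[ord[i]];
      suml += 2.0 * lc[c] + 1.0;
      lc[c]++;
      const double xv = X(ord[i], f), xn = X(ord[i + 1], f);
      if (!(xn > xv)) continue;
      const int nl = i + 1, nr = n - nl;
      double sumr = 0.0;
      for (int k = 0; k < K; ++k) {
        const double d = cnt[k] - lc[k];
        sumr += d * d;
      }
      const double score = suml / nl + sumr / nr;
      if (score > best_score + 1e-12) {
        best_score = score;
        best_f = f;
        best_thr = 0.5 * (xv + xn);
      }
    }
  }
  if (best_f < 0) return node;  // no impurity-reducing split exists

  std::vector<int> L, R2;
  L.reserve(n);
  R2.reserve(n);
  for (int i = lo; i < hi; ++i) {
    if (X(idx[i], best_f) <= best_thr) L.push_back(idx[i]);
    else R2.push_back(idx[i]);
  }
  std::copy(L.begin(), L.end(), idx.begin() + lo);
  std::copy(R2.begin(), R2.end(), idx.begin() + lo + L.size());
  T.feat[node] = best_f;
  T.thr[node] = best_thr;
  const int lchild =
      grow_node(X, y, K, idx, lo, lo + (int)L.size(), mtry, min_node, fpool, T);
  const int rchild =
      grow_node(X, y, K, idx, lo + (int)L.size(), hi, mtry, min_node, fpool, T);
  T.left[node] = lchild;
  T.right[node] = rchild;
  return node;
}

}  // namespace

// [[Rcpp::export]]
List cpp_rf_grow(NumericMatrix X, IntegerVector y, int K, int ntree, int mtry,
                 int min_node) {
  const int n = X.nrow();
  List forest(ntree);
  std::vector<int> fpool(X.ncol());
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int r = (int)(unif_rand() * n);
      if (r >= n) r = n - 1;
      idx[i] = r;
    }
    TreeBuf T;
    grow_node(X, y, K, idx, 0, n, mtry, min_node, fpool, T);
    forest[t] = List::create(
        _["feat"] = IntegerVector(T.feat.begin(), T.feat.end()),
        _["thr"] = NumericVector(T.thr.begin(), T.thr.end()),
        _["left"] = IntegerVector(T.left.begin(), T.left.end()),
        _["right"] = IntegerVector(T.right.begin(), T.right.end()),
        _["pred"] = IntegerVector(T.pred.begin(), T.pred.end()));
  }
  return forest;
}

// [[Rcpp::export]]
NumericMatrix cpp_rf_votes(List forest, NumericMatrix X, int K) {
  const int n = X.nrow();
  NumericMatrix votes(n, K);
  for (int t = 0; t < forest.size(); ++t) {
    List tree = forest[t];
    IntegerVector feat = tree["feat"];
    NumericVector thr = tree["thr"];
    IntegerVector left = tree["left"];
    IntegerVector right = tree["right"];
    IntegerVector pred = tree["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0)
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      votes(i, pred[node]) += 1.0;
    }
  }
  return votes;
}
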