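#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Chebyshev (max-norm) distance between rows a of X and b of Y
static inline double cheby(const NumericMatrix& X, int a,
                           const NumericMatrix& Y, int b) {
  double d = 0.0;
  const int p = X.ncol();
  for (int j = 0; j < p; ++j) {
    double v = std::fabs(X(a, j) - Y(b, j));
    if (v > d) d = v;
  }
  return d;
}

// Distance to the k-th nearest neighbour (self excluded) of each row of X,
// among the rows of X, in the Chebyshev metric.
// [[Rcpp::export]]
NumericVector cheby_knn_dist(NumericMatrix X, int k) {
  const int n = X.nrow();
  if (k < 1 || k > n - 1) stop("need 1 <= k <= nrow(X) - 1");
  NumericVector out(n);
  std::vector<double> d(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      d[m++] = cheby(X, i, X, j);
    }
    std::nth_element(d.begin(), d.begin() + (k - 1), d.end());
    out[i] = d[k - 1];
  }
  return out;
}

// For each query row i of X (with radius eps[i]) and each category c,
// count rows of the category-c matrix strictly within Chebyshev distance
// eps[i]. `cats` is a list of numeric matrices, all with ncol(X) columns.
// `self_cat`/`self_idx` (0-based; self_idx = -1 to disable) identify the
// query point inside its own category matrix so it is not counted.
// [[Rcpp::export]]
IntegerMatrix cheby_count_within(NumericMatrix X, NumericVector eps,
                                 List cats, IntegerVector self_cat,
                                 IntegerVector self_idx) {
  const int n = X.nrow();
  const int C = cats.size();
  IntegerMatrix out(n, C);
  for (int c = 0; c < C; ++c) {
    NumericMatrix Yc = cats[c];
    for (int i = 0; i < n; ++i) {
      const double e = eps[i];
      int cnt = 0;
      for (int j = 0; j < Yc.nrow(); ++j) {
        if (self_cat[i] == c && self_idx[i] == j) continue;
        if (cheby(X, i, Yc, j) < e) ++cnt;
      }
      out(i, c) = cnt;
    }
  }
  return out;
}
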