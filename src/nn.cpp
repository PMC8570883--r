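#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Nearest neighbour in `ref` for every row of `query`. Brute force on
// purpose: clouds here are <= ~10k points, and an O(n*m) loop in C++ beats
// tree construction overhead at that size. Works for any dimension.
// [[Rcpp::export]]
List cpp_nn1(NumericMatrix query, NumericMatrix ref) {
  const int n = query.nrow(), m = ref.nrow(), d = query.ncol();
  if (m == 0) stop("reference set is empty");
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double t = query(i, k) - ref(j, k);
        s += t * t;
      }
      if (s < best) { best = s; bj = j; }  // ties: lowest index wins
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Mean distance from each point to its k nearest neighbours (self excluded).
// [[Rcpp::export]]
NumericVector cpp_knn_mean_dist(NumericMatrix pts, int k) {
  const int n = pts.nrow(), d = pts.ncol();
  if (k <= 0) stop("k must be positive");
  if (k >= n) stop("k must be smaller than the number of points");
  NumericVector out(n);
  std::vector<double> dd(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double t = pts(i, c) - pts(j, c);
        s += t * t;
      }
      dd[j] = s;
    }
    dd[i] = R_PosInf;
    std::nth_element(dd.begin(), dd.begin() + (k - 1), dd.end());
    double acc = 0.0;
    for (int j = 0; j < k; ++j) acc += std::sqrt(dd[j]);
    out[i] = acc / k;
  }
  return out;
}
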