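#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Relief-F weights (Kononenko 1994): for every instance, subtract the mean
// normalised difference to its k nearest same-class neighbours ("hits") and
// add, per other class, the prior-weighted mean difference to its k nearest
// neighbours of that class ("misses"). All instances are used (m = U).
// Neighbour counts degrade gracefully when a class has fewer members than k.

static double sum_k_smallest(std::vector<double>& v, int k) {
  if ((int)v.size() > k)
    std::nth_element(v.begin(), v.begin() + k, v.end());
  double s = 0.0;
  int n = std::min<int>(k, v.size());
  for (int i = 0; i < n; ++i) s += v[i];
  return s;
}

// One weight per column of M, each column scored in its own 1-D space
// (distance between instances = absolute difference of that column).
// cls is 1-based class index.
// [[Rcpp::export]]
NumericVector relief_1d_cols(const NumericMatrix& M, const IntegerVector& cls,
                             int k) {
  const int U = M.nrow(), V = M.ncol();
  int N = 0;
  for (int i = 0; i < U; ++i) N = std::max(N, cls[i]);
  std::vector<int> nc(N, 0);
  for (int i = 0; i < U; ++i) nc[cls[i] - 1]++;
  std::vector<double> prior(N);
  for (int c = 0; c < N; ++c) prior[c] = (double)nc[c] / U;

  NumericVector W(V);
  std::vector<double> d;
  for (int j = 0; j < V; ++j) {
    NumericMatrix::ConstColumn x = M.column(j);
    double lo = x[0], hi = x[0];
    for (int i = 1; i < U; ++i) { lo = std::min(lo, x[i]); hi = std::max(hi, x[i]); }
    double range = hi - lo;
    if (range <= 0.0) { W[j] = 0.0; continue; }
    double w = 0.0;
    for (int i = 0; i < U; ++i) {
      int ci = cls[i] - 1;
      for (int c = 0; c < N; ++c) {
        d.clear();
        for (int t = 0; t < U; ++t)
          if (t != i && cls[t] - 1 == c)
            d.push_back(std::fabs(x[t] - x[i]));
        if (d.empty()) continue;
        if (c == ci) {
          int kh = std::min<int>(k, d.size());
          w -= sum_k_smallest(d, kh) / range / ((double)U * kh);
        } else {
          int km = std::min<int>(k, d.size());
          w += prior[c] / (1.0 - prior[ci]) *
               sum_k_smallest(d, km) / range / ((double)U * km);
        }
      }
    }
    W[j] = w;
  }
  return W;
}

// Native multivariate Relief-F over a full samples x genes matrix:
// features min-max normalised, neighbours found by Manhattan distance in the
// normalised space, per-feature differences accumulated for the chosen
// neighbours. Returns one weight per gene.
// [[Rcpp::export]]
NumericVector relief_matrix(const NumericMatrix& X, const IntegerVector& cls,
                            int k) {
  const int U = X.nrow(), V = X.ncol();
  int N = 0;
  for (int i = 0; i < U; ++i) N = std::max(N, cls[i]);
  std::vector<int> nc(N, 0);
  for (int i = 0; i < U; ++i) nc[cls[i] - 1]++;
  std::vector<double> prior(N);
  for (int c = 0; c < N; ++c) prior[c] = (double)nc[c] / U;

  // normalise a copy column-wise to [0, 1]
  NumericMatrix Z(U, V);
  for (int j = 0; j < V; ++j) {
    double lo = X(0, j), hi = X(0, j);
    for (int i = 1; i < U; ++i) { lo = std::min(lo, X(i, j)); hi = std::max(hi, X(i, j)); }
    double range = hi - lo;
    for (int i = 0; i < U; ++i)
      Z(i, j) = range > 0.0 ? (X(i, j) - lo) / range : 0.0;
  }

  NumericVector W(V);
  std::vector<std::pair<double, int> > d;
  for (int i = 0; i < U; ++i) {
    int ci = cls[i] - 1;
    for (int c = 0; c < N; ++c) {
      d.clear();
      for (int t = 0; t < U; ++t) {
        if (t == i || cls[t] - 1 != c) continue;
        double dist = 0.0;
        for (int j = 0; j < V; ++j) dist += std::fabs(Z(t, j) - Z(i, j));
        d.push_back(std::make_pair(dist, t));
      }
      if (d.empty()) continue;
      int kk = std::min<int>(k, d.size());
      if ((int)d.size() > kk)
        std::nth_element(d.begin(), d.begin() + kk, d.end());
      double coef = (c == ci) ? -1.0 / ((double)U * kk)
                              : prior[c] / (1.0 - prior[ci]) / ((double)U * kk);
      for (int q = 0; q < kk; ++q) {
        int t = d[q].second;
        for (int j = 0; j < V; ++j)
          W[j] += coef * std::fabs(Z(t, j) - Z(i, j));
      }
    }
  }
  return W;
}
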