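#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// k-nearest-neighbor search under the maximum norm with a temporal
// (Theiler) exclusion window. Rows of X are embedding vectors indexed by
// beat counter; rows m with |m - n| <= T are never neighbors of row n.
// Ties in distance are broken in favor of the smaller row index: the scan
// runs over ascending m and an incumbent at equal distance is kept.
// Early abandonment: the running max-norm distance is compared against the
// current k-th distance so most far rows are rejected after few columns.
static void knn_query(const NumericMatrix& X, int n, int k, int T,
                      std::vector<int>& idx, std::vector<double>& dist) {
  const int N = X.nrow(), q = X.ncol();
  int filled = 0;
  for (int m = 0; m < N; ++m) {
    int sep = m > n ? m - n : n - m;
    if (sep <= T) continue;
    const double worst = (filled == k) ? dist[k - 1] : R_PosInf;
    double d = 0.0;
    bool far = false;
    for (int c = 0; c < q; ++c) {
      double diff = X(m, c) - X(n, c);
      if (diff < 0) diff = -diff;
      if (diff > d) {
        d = diff;
        if (d >= worst) { far = true; break; }
      }
    }
    if (far || d >= worst) continue;
    int pos = (filled < k) ? filled : k - 1;
    while (pos > 0 && dist[pos - 1] > d) {
      dist[pos] = dist[pos - 1];
      idx[pos] = idx[pos - 1];
      --pos;
    }
    dist[pos] = d;
    idx[pos] = m;
    if (filled < k) ++filled;
  }
  if (filled < k)
    stop("fewer than k admissible rows in the neighbor search (row %d: %d < %d)",
         n + 1, filled, k);
}

// [[Rcpp::export]]
List cpp_knn_query(NumericMatrix X, int n, int k, int T) {
  std::vector<int> idx(k);
  std::vector<double> dist(k);
  knn_query(X, n - 1, k, T, idx, dist);
  IntegerVector oi(k);
  NumericVector od(k);
  for (int a = 0; a < k; ++a) { oi[a] = idx[a] + 1; od[a] = dist[a]; }
  return List::create(_["index"] = oi, _["dist"] = od);
}

// Leave-self-out zero-order prediction of y over every row of X: the
// inverse-distance weighted mean of the images of the k nearest admissible
// rows. An exact match (distance 0) dominates: the prediction is the plain
// mean of the zero-distance images (the limit of inverse-distance weights).
// [[Rcpp::export]]
NumericVector cpp_lp_predict(NumericMatrix X, NumericVector y, int k, int T) {
  const int N = X.nrow();
  NumericVector out(N);
  std::vector<int> idx(k);
  std::vector<double> dist(k);
  for (int n = 0; n < N; ++n) {
    knn_query(X, n, k, T, idx, dist);
    double s = 0.0;
    int nz = 0;
    for (int a = 0; a < k; ++a)
      if (dist[a] == 0.0) { s += y[idx[a]]; ++nz; }
    if (nz > 0) { out[n] = s / nz; continue; }
    double num = 0.0, den = 0.0;
    for (int a = 0; a < k; ++a) {
      double w = 1.0 / dist[a];
      num += w * y[idx[a]];
      den += w;
    }
    out[n] = num / den;
  }
  return out;
}

// k-NN conditional entropy: for every row the conditional sample is the set
// of images of its k nearest neighbors; the per-row Shannon entropy is the
// negative log of the fraction of unordered distinct image pairs closer
// than eps (floored at one pair so the estimate stays finite), averaged
// over rows.
// [[Rcpp::export]]
double cpp_ce_mean(NumericMatrix X, NumericVector y, int k, int T, double eps) {
  const int N = X.nrow();
  const double npairs = k * (k - 1) / 2.0;
  std::vector<int> idx(k);
  std::vector<double> dist(k);
  double acc = 0.0;
  for (int n = 0; n < N; ++n) {
    knn_query(X, n, k, T, idx, dist);
    int cnt = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b) {
        double diff = y[idx[a]] - y[idx[b]];
        if (diff < 0) diff = -diff;
        if (diff <= eps) ++cnt;
      }
    double p = cnt / npairs;
    if (p <= 0.0) p = 1.0 / npairs;
    acc += -std::log(p);
  }
  return acc / N;
}
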