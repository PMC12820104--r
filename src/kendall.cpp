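#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// merge sort counting inversions in y (pairs i<j with y[i] > y[j])
static double count_inversions(std::vector<double>& y, std::vector<double>& buf,
                               int lo, int hi) {
  if (hi - lo < 2) return 0.0;
  int mid = (lo + hi) / 2;
  double inv = count_inversions(y, buf, lo, mid) +
               count_inversions(y, buf, mid, hi);
  int i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (y[i] <= y[j]) buf[k++] = y[i++];
    else { inv += mid - i; buf[k++] = y[j++]; }
  }
  while (i < mid) buf[k++] = y[i++];
  while (j < hi) buf[k++] = y[j++];
  std::copy(buf.begin() + lo, buf.begin() + k, y.begin() + lo);
  return inv;
}

// Kendall tau-a by inversion counting, O(n log n); assumes continuous data
// (no ties in x or y)
// [[Rcpp::export(name = ".kendall_tau_notie")]]
double kendall_tau_notie(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n != y.size()) stop("x and y must have the same length");
  if (n < 2) return NA_REAL;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  std::vector<double> ys(n), buf(n);
  for (int i = 0; i < n; ++i) ys[i] = y[idx[i]];
  double inv = count_inversions(ys, buf, 0, n);
  double total = (double)n * (n - 1) / 2.0;
  return 1.0 - 2.0 * inv / total;
}
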