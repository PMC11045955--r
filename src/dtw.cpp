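#include <Rcpp.h>
using namespace Rcpp;

// Cumulative cost matrix of the DTW dynamic program.
// Boundary: C(1,1) = D(1,1); first row/column are prefix sums; interior
// C(i,j) = D(i,j) + min(C(i-1,j), C(i,j-1), C(i-1,j-1)).
// [[Rcpp::export(name = ".dtw_cumulative_cpp")]]
NumericMatrix dtw_cumulative_cpp(NumericMatrix D) {
  const int m = D.nrow(), n = D.ncol();
  NumericMatrix C(m, n);
  C(0, 0) = D(0, 0);
  for (int i = 1; i < m; ++i) C(i, 0) = D(i, 0) + C(i - 1, 0);
  for (int j = 1; j < n; ++j) C(0, j) = D(0, j) + C(0, j - 1);
  for (int i = 1; i < m; ++i) {
    for (int j = 1; j < n; ++j) {
      double best = C(i - 1, j - 1);
      if (C(i - 1, j) < best) best = C(i - 1, j);
      if (C(i, j - 1) < best) best = C(i, j - 1);
      C(i, j) = D(i, j) + best;
    }
  }
  return C;
}

// DTW distance between two multichannel sequences (columns are samples,
// rows are channels) with vector Euclidean pointwise cost and a shared
// warping path. Only the distance is computed (two rolling rows), which is
// the classifier's hot path. An optional Sakoe-Chiba band (window >= 0, in
// samples around the diagonal) restricts the warp; window < 0 means
// unconstrained.
// [[Rcpp::export(name = ".mdtw_dist_cpp")]]
double mdtw_dist_cpp(NumericMatrix x, NumericMatrix y, int window) {
  const int d = x.nrow(), m = x.ncol(), n = y.ncol();
  if (y.nrow() != d) stop("channel count mismatch");
  const double inf = R_PosInf;
  std::vector<double> prev(n), cur(n);
  double slope = static_cast<double>(n) / m;
  for (int i = 0; i < m; ++i) {
    int jlo = 0, jhi = n - 1;
    if (window >= 0) {
      int centre = static_cast<int>(std::floor(i * slope));
      jlo = std::max(0, centre - window);
      jhi = std::min(n - 1, centre + window);
    }
    for (int j = 0; j < n; ++j) cur[j] = inf;
    for (int j = jlo; j <= jhi; ++j) {
      double acc = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = x(k, i) - y(k, j);
        acc += diff * diff;
      }
      const double cost = std::sqrt(acc);
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else if (i == 0) {
        best = cur[j - 1];
      } else if (j == 0) {
        best = prev[0];
      } else {
        best = prev[j - 1];
        if (prev[j] < best) best = prev[j];
        if (cur[j - 1] < best) best = cur[j - 1];
      }
      cur[j] = cost + best;
    }
    std::swap(prev, cur);
  }
  return prev[n - 1];
}
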