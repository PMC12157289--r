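#include <Rcpp.h>
using namespace Rcpp;

// Cumulative DTW cost under the symmetric step pattern with diagonal weight
// 2: D(1,1) = d(1,1); D(i,j) = min(D(i-1,j-1) + 2 d, D(i-1,j) + d,
// D(i,j-1) + d) with local cost d(i,j) = |x_i - y_j|. Returns the raw
// (unnormalised) cost D(n,m). Two-row rolling buffer.
// [[Rcpp::export]]
double dtw_raw_cost(NumericVector x, NumericVector y) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("series must be non-empty");
  std::vector<double> prev(m), cur(m);
  prev[0] = std::abs(x[0] - y[0]);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + std::abs(x[0] - y[j]);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + std::abs(x[i] - y[0]);
    for (int j = 1; j < m; ++j) {
      const double d = std::abs(x[i] - y[j]);
      double best = prev[j - 1] + 2.0 * d;          // diagonal
      const double up = prev[j] + d;                // insertion
      const double left = cur[j - 1] + d;           // deletion
      if (up < best) best = up;
      if (left < best) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Full matrix of length-normalised DTW distances, cost / (n + m), over all
// unordered pairs; diagonal zero.
// [[Rcpp::export]]
NumericMatrix dtw_pairwise_norm(List series) {
  const int n = series.size();
  std::vector<NumericVector> sv(n);
  for (int i = 0; i < n; ++i) sv[i] = as<NumericVector>(series[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double c = dtw_raw_cost(sv[i], sv[j]) /
        (double)(sv[i].size() + sv[j].size());
      out(i, j) = c;
      out(j, i) = c;
    }
  }
  return out;
}
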