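#include <Rcpp.h>
#include <vector>
#include <cmath>

// Classic dynamic-time-warping alignment of two 2D point sequences with
// Euclidean local cost and steps {(i-1,j), (i,j-1), (i-1,j-1)}, no window.
// Returns the accumulated cost along the optimal monotone warping path.
// [[Rcpp::export]]
double dtw_distance_cpp(Rcpp::NumericVector ex, Rcpp::NumericVector ey,
                        Rcpp::NumericVector rx, Rcpp::NumericVector ry) {
  const int n = ex.size(), m = rx.size();
  if (n == 0 || m == 0) Rcpp::stop("empty sequence");
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = inf;
    const double xi = ex[i - 1], yi = ey[i - 1];
    for (int j = 1; j <= m; ++j) {
      const double dx = xi - rx[j - 1], dy = yi - ry[j - 1];
      const double cost = std::sqrt(dx * dx + dy * dy);
      double best = prev[j - 1];            // diagonal
      if (prev[j] < best) best = prev[j];   // insertion
      if (cur[j - 1] < best) best = cur[j - 1];  // deletion
      cur[j] = cost + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
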