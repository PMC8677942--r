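#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dynamic-programming DTW cost between univariate series.
// Step set {(1,0),(0,1),(1,1)}; local cost |x_i - y_j| (or squared).
// band < 0 means unbounded; otherwise a Sakoe-Chiba band of half-width `band`
// around the (stretched) diagonal |i - j| <= band (indices 0-based).
// [[Rcpp::export(name = ".dtw_cost_cpp")]]
double dtw_cost_cpp(NumericVector x, NumericVector y, int band, bool squared) {
  const int n = x.size(), m = y.size();
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), inf);
    int jlo = 1, jhi = m;
    if (band >= 0) {
      jlo = std::max(1, i - band);
      jhi = std::min(m, i + band);
      if (jlo > jhi) { prev.swap(cur); continue; }
    }
    for (int j = jlo; j <= jhi; ++j) {
      double d = std::fabs(x[i - 1] - y[j - 1]);
      if (squared) d *= d;
      double best = prev[j];                    // (1,0) insertion
      if (cur[j - 1] < best) best = cur[j - 1]; // (0,1) deletion
      if (prev[j - 1] < best) best = prev[j - 1]; // (1,1) match
      cur[j] = d + best;
    }
    prev.swap(cur);
  }
  return prev[m];
}

// Independent oracle: exhaustive enumeration of all monotone warping paths
// from (0,0) to (n-1,m-1) with the same step set. Exponential; only for tiny
// series in tests. Deliberately a different algorithm from the DP above.
static double brute_rec(const NumericVector& x, const NumericVector& y,
                        int i, int j, bool squared) {
  double d = std::fabs(x[i] - y[j]);
  if (squared) d *= d;
  const int n = x.size(), m = y.size();
  if (i == n - 1 && j == m - 1) return d;
  double best = std::numeric_limits<double>::infinity();
  if (i + 1 < n) best = std::min(best, brute_rec(x, y, i + 1, j, squared));
  if (j + 1 < m) best = std::min(best, brute_rec(x, y, i, j + 1, squared));
  if (i + 1 < n && j + 1 < m)
    best = std::min(best, brute_rec(x, y, i + 1, j + 1, squared));
  return d + best;
}

// [[Rcpp::export(name = ".dtw_brute_cpp")]]
double dtw_brute_cpp(NumericVector x, NumericVector y, bool squared) {
  if (x.size() == 0 || y.size() == 0) stop("empty series");
  if (x.size() > 8 || y.size() > 8) stop("brute-force oracle limited to length <= 8");
  return brute_rec(x, y, 0, 0, squared);
}
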