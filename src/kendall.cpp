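// Kendall's tau-b by direct O(n^2) pair counting:
//   tau = (nc - nd) / sqrt((nc + nd + T) * (nc + nd + U))
// where T counts pairs tied in `b` only and U pairs tied in `a` only
// (pairs tied in both are excluded from every term). Returns NA when either
// side of the denominator is zero (one argument entirely tied).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
double kendall_tau_b_cpp(NumericVector a, NumericVector b) {
  int n = a.size();
  if (b.size() != n) stop("length mismatch");
  double nc = 0, nd = 0, ta = 0, tb = 0;  // ta: tied in a only; tb: tied in b only
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double da = a[i] - a[j], db = b[i] - b[j];
      if (da == 0 && db == 0) continue;
      if (da == 0) { ta += 1; continue; }
      if (db == 0) { tb += 1; continue; }
      if (da * db > 0) nc += 1; else nd += 1;
    }
  }
  double d1 = nc + nd + tb;  // pairs not tied in a
  double d2 = nc + nd + ta;  // pairs not tied in b
  if (d1 <= 0 || d2 <= 0) return NA_REAL;
  return (nc - nd) / std::sqrt(d1 * d2);
}
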