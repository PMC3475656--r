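#include <Rcpp.h>
using namespace Rcpp;

// Victor-Purpura spike-train edit distance: insert/delete cost 1, shifting a
// spike by dt costs q*|dt|. Standard O(n*m) dynamic program over the two
// sorted spike-time vectors.
// [[Rcpp::export(name = ".vp_distance_cpp")]]
double vp_distance_cpp(NumericVector a, NumericVector b, double q) {
  int n = a.size(), m = b.size();
  if (n == 0) return (double)m;
  if (m == 0) return (double)n;
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      double shift = prev[j - 1] + q * std::fabs(a[i - 1] - b[j - 1]);
      double del = prev[j] + 1.0;
      double ins = cur[j - 1] + 1.0;
      cur[j] = std::min(shift, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// All pairwise VP distances of a list of sorted spike-time vectors.
// [[Rcpp::export(name = ".vp_matrix_cpp")]]
NumericMatrix vp_matrix_cpp(List trains, double q) {
  int n = trains.size();
  NumericMatrix d(n, n);
  std::vector<NumericVector> tr(n);
  for (int i = 0; i < n; ++i) tr[i] = as<NumericVector>(trains[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double v = vp_distance_cpp(tr[i], tr[j], q);
      d(i, j) = v;
      d(j, i) = v;
    }
  }
  return d;
}
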