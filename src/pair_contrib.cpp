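#include <Rcpp.h>
using namespace Rcpp;

// Per-taxon contribution to summed pairwise Bray-Curtis similarity:
// W_t = sum_{i<j} 2 * min(x_it, x_jt) / (tot_i + tot_j),
// where tot are full-community sample totals supplied by the caller so the
// similarity of any top-k taxon subset is a true fraction of the total.
// [[Rcpp::export]]
NumericVector pair_min_colsums(NumericMatrix x, NumericVector totals) {
  const int n = x.nrow(), p = x.ncol();
  if (totals.size() != n) stop("totals length must equal nrow(x)");
  NumericVector w(p);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double denom = totals[i] + totals[j];
      if (denom <= 0) continue;
      const double f = 2.0 / denom;
      for (int t = 0; t < p; ++t) {
        const double a = x(i, t), b = x(j, t);
        w[t] += f * (a < b ? a : b);
      }
    }
  }
  return w;
}
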