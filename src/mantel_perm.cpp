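#include <Rcpp.h>
using namespace Rcpp;

// Pearson correlations between a fixed unfolded upper triangle `a` and the
// upper triangle of B[p, p] for each permutation p (columns of `perms`,
// 0-based). B must be symmetric with zero diagonal; the multiset of its
// upper-triangle values is invariant under joint row/column relabeling, so
// the permuted mean and spread are precomputed once.
// [[Rcpp::export]]
NumericVector mantel_perm_cor(NumericVector a, NumericMatrix B,
                              IntegerMatrix perms) {
  const int n = B.nrow();
  const int np = perms.ncol();
  const R_xlen_t m = (R_xlen_t)n * (n - 1) / 2;
  if (a.size() != m) stop("length of a does not match B");
  if (perms.nrow() != n) stop("permutation rows must match B");

  double ma = 0.0, mb = 0.0;
  for (R_xlen_t k = 0; k < m; ++k) ma += a[k];
  ma /= m;
  {
    R_xlen_t k = 0;
    for (int j = 1; j < n; ++j)
      for (int i = 0; i < j; ++i, ++k) mb += B(i, j);
    mb /= m;
  }
  double ssa = 0.0, ssb = 0.0;
  for (R_xlen_t k = 0; k < m; ++k) ssa += (a[k] - ma) * (a[k] - ma);
  {
    R_xlen_t k = 0;
    for (int j = 1; j < n; ++j)
      for (int i = 0; i < j; ++i, ++k) ssb += (B(i, j) - mb) * (B(i, j) - mb);
  }
  const double denom = std::sqrt(ssa * ssb);
  if (denom <= 0) stop("zero variance in a distance matrix");

  NumericVector out(np);
  const double *b = B.begin();
  for (int t = 0; t < np; ++t) {
    const int *p = &perms(0, t);
    double s = 0.0;
    R_xlen_t k = 0;
    for (int j = 1; j < n; ++j) {
      const double *bcol_base = b;  // index B[p[i], p[j]] column-major
      const R_xlen_t pj = (R_xlen_t)p[j] * n;
      for (int i = 0; i < j; ++i, ++k) {
        s += a[k] * bcol_base[pj + p[i]];
      }
    }
    out[t] = (s - m * ma * mb) / denom;
  }
  return out;
}
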