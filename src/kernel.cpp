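#include <Rcpp.h>
using namespace Rcpp;

// All-substrings kernel via the suffix-product recurrence
//   M(i, j) = B(f_i, g_j) * (1 + M(i+1, j+1)),   cdr = sum_{i,j} M(i, j).
// M(i, j) accumulates the scores of every equal-length substring pair
// starting at (i, j); summing over all start positions covers all k.
static double cdr_raw_core(const IntegerVector& f, const IntegerVector& g,
                           const NumericMatrix& B) {
  const int n = f.size(), m = g.size();
  std::vector<double> nxt(m + 1, 0.0), cur(m + 1, 0.0);
  double total = 0.0;
  for (int i = n - 1; i >= 0; --i) {
    cur[m] = 0.0;
    const int fi = f[i] - 1;
    for (int j = m - 1; j >= 0; --j) {
      const double b = B(fi, g[j] - 1);
      cur[j] = b * (1.0 + nxt[j + 1]);
      total += cur[j];
    }
    std::swap(cur, nxt);
  }
  return total;
}

// [[Rcpp::export]]
double cdr_raw_dp(IntegerVector f, IntegerVector g, NumericMatrix B) {
  if (f.size() == 0 || g.size() == 0)
    stop("loop sequences must be non-empty");
  return cdr_raw_core(f, g, B);
}

// [[Rcpp::export]]
NumericMatrix cdr_raw_cross_dp(List fs, List gs, NumericMatrix B) {
  const int n = fs.size(), m = gs.size();
  std::vector<IntegerVector> ef(n), eg(m);
  for (int i = 0; i < n; ++i) ef[i] = as<IntegerVector>(fs[i]);
  for (int j = 0; j < m; ++j) eg[j] = as<IntegerVector>(gs[j]);
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      out(i, j) = cdr_raw_core(ef[i], eg[j], B);
  return out;
}

// Mutual-nearest alpha-carbon RMSD between two loops already in a common
// frame. For each atom a1 of loop A the nearest atom a2 of loop B is found,
// then the nearest atom of A to a2; only if that is a1 again (a mutual
// nearest pair) does the pair contribute its squared distance. Distance
// ties resolve to the lowest atom index (atoms are supplied in residue
// order). Returns [rmsd, n_pairs]; rmsd is NaN when no mutual pair exists.
// [[Rcpp::export]]
NumericVector mutual_nn_rmsd(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  if (n == 0 || m == 0) stop("empty loop");
  auto d2 = [&](int i, int j) {
    const double dx = A(i, 0) - B(j, 0);
    const double dy = A(i, 1) - B(j, 1);
    const double dz = A(i, 2) - B(j, 2);
    return dx * dx + dy * dy + dz * dz;
  };
  double sum = 0.0;
  int count = 0;
  for (int i = 0; i < n; ++i) {
    int best_j = 0; double best = d2(i, 0);
    for (int j = 1; j < m; ++j) {
      const double d = d2(i, j);
      if (d < best) { best = d; best_j = j; }
    }
    int back_i = 0; double back = d2(0, best_j);
    for (int i2 = 1; i2 < n; ++i2) {
      const double d = d2(i2, best_j);
      if (d < back) { back = d; back_i = i2; }
    }
    if (back_i == i) { sum += best; ++count; }
  }
  NumericVector out(2);
  out[0] = count > 0 ? std::sqrt(sum / count) : R_NaN;
  out[1] = count;
  return out;
}
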