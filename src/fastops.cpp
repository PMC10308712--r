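#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam update for one parameter leaf.  The caller owns the
// aliasing discipline: p, m and v must not be shared with any object that
// R-level code still treats as immutable.
// [[Rcpp::export(rng = false)]]
void adamUpdateInplace(NumericVector p, NumericVector g, NumericVector m,
                       NumericVector v, int t, double lr, double beta1,
                       double beta2, double eps) {
  const R_xlen_t n = p.size();
  if (g.size() != n || m.size() != n || v.size() != n)
    stop("adamUpdateInplace: length mismatch");
  const double c1 = 1.0 - std::pow(beta1, (double)t);
  const double c2 = 1.0 - std::pow(beta2, (double)t);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i];
    const double mi = beta1 * m[i] + (1.0 - beta1) * gi;
    const double vi = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    m[i] = mi;
    v[i] = vi;
    p[i] -= lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
}

// Copy src into dest in place (same length); used to restore the
// best-validation parameters without reallocating the tree.
// [[Rcpp::export(rng = false)]]
void copyInplace(NumericVector dest, NumericVector src) {
  if (dest.size() != src.size()) stop("copyInplace: length mismatch");
  std::copy(src.begin(), src.end(), dest.begin());
}
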