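#include <Rcpp.h>
using namespace Rcpp;

// Kernels for the symmetric tridiagonal mass operator M = L + A^2 acting on
// the interior nodes of a path (Dirichlet: values at both path endpoints are
// zero).  Each spatial dimension has a constant diagonal dg = A^2 + 2/dt^2
// and off-diagonal off = -1/dt^2, so the operator is a constant-coefficient
// tridiagonal matrix per column of the (n x d) interior array.

// [[Rcpp::export]]
NumericMatrix tridiag_apply_cpp(NumericMatrix x, NumericVector dg, double off) {
  const int n = x.nrow(), d = x.ncol();
  NumericMatrix y(n, d);
  for (int k = 0; k < d; ++k) {
    const double a = dg[k];
    if (n == 1) { y(0, k) = a * x(0, k); continue; }
    y(0, k) = a * x(0, k) + off * x(1, k);
    for (int i = 1; i < n - 1; ++i)
      y(i, k) = off * x(i - 1, k) + a * x(i, k) + off * x(i + 1, k);
    y(n - 1, k) = off * x(n - 2, k) + a * x(n - 1, k);
  }
  return y;
}

// Cholesky factor M = C C^T with C lower bidiagonal: C has diagonal l and
// sub-diagonal e.  This is Gaussian elimination without pivoting, which is
// stable here because M is strictly diagonally dominant for A >= 0.
// [[Rcpp::export]]
List tridiag_chol_cpp(int n, NumericVector dg, double off) {
  const int d = dg.size();
  NumericMatrix l(n, d), e(std::max(n - 1, 1), d);
  for (int k = 0; k < d; ++k) {
    double li = std::sqrt(dg[k]);
    l(0, k) = li;
    for (int i = 1; i < n; ++i) {
      const double ei = off / li;
      e(i - 1, k) = ei;
      const double piv = dg[k] - ei * ei;
      if (piv <= 0.0) stop("mass operator factorization lost positive definiteness");
      li = std::sqrt(piv);
      l(i, k) = li;
    }
  }
  return List::create(_["l"] = l, _["e"] = e);
}

// Solve (C C^T) x = b given the bidiagonal factor.
// [[Rcpp::export]]
NumericMatrix tridiag_chol_solve_cpp(NumericMatrix l, NumericMatrix e,
                                     NumericMatrix b) {
  const int n = b.nrow(), d = b.ncol();
  NumericMatrix x(n, d);
  for (int k = 0; k < d; ++k) {
    // forward: C y = b
    x(0, k) = b(0, k) / l(0, k);
    for (int i = 1; i < n; ++i)
      x(i, k) = (b(i, k) - e(i - 1, k) * x(i - 1, k)) / l(i, k);
    // backward: C^T x = y
    x(n - 1, k) /= l(n - 1, k);
    for (int i = n - 2; i >= 0; --i)
      x(i, k) = (x(i, k) - e(i, k) * x(i + 1, k)) / l(i, k);
  }
  return x;
}

// Solve C^T v = z.  If z is a standard-normal draw and the precision matrix
// is C C^T, then v has covariance (C C^T)^{-1}: one back-substitution turns
// white noise into a pinned (bridge) Gaussian path.
// [[Rcpp::export]]
NumericMatrix tridiag_backsolve_t_cpp(NumericMatrix l, NumericMatrix e,
                                      NumericMatrix z) {
  const int n = z.nrow(), d = z.ncol();
  NumericMatrix v(n, d);
  for (int k = 0; k < d; ++k) {
    v(n - 1, k) = z(n - 1, k) / l(n - 1, k);
    for (int i = n - 2; i >= 0; --i)
      v(i, k) = (z(i, k) - e(i, k) * v(i + 1, k)) / l(i, k);
  }
  return v;
}
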