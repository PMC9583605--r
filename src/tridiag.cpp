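#include <Rcpp.h>
using namespace Rcpp;

// Thomas algorithm for tridiagonal systems.
// a: sub-diagonal (a[0] unused), b: diagonal, c: super-diagonal
// (c[n-1] unused), r: right-hand side.
// [[Rcpp::export]]
NumericVector thomas_solve(NumericVector a, NumericVector b,
                           NumericVector c, NumericVector r) {
  int n = b.size();
  NumericVector cp(n), rp(n), x(n);
  cp[0] = c[0] / b[0];
  rp[0] = r[0] / b[0];
  for (int i = 1; i < n; ++i) {
    double den = b[i] - a[i] * cp[i - 1];
    cp[i] = c[i] / den;
    rp[i] = (r[i] - a[i] * rp[i - 1]) / den;
  }
  x[n - 1] = rp[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = rp[i] - cp[i] * x[i + 1];
  return x;
}

// Batched Thomas solves: k systems of size n, stored column-wise.
// a, b, c, r are n x k matrices (a(0,j), c(n-1,j) unused).
// [[Rcpp::export]]
NumericMatrix thomas_solve_many(NumericMatrix a, NumericMatrix b,
                                NumericMatrix c, NumericMatrix r) {
  int n = b.nrow(), k = b.ncol();
  NumericMatrix x(n, k);
  std::vector<double> cp(n), rp(n);
  const double *pa = a.begin(), *pb = b.begin(), *pc = c.begin(),
               *pr = r.begin();
  double *px = x.begin();
  for (int j = 0; j < k; ++j) {
    const double *aj = pa + (std::size_t)j * n, *bj = pb + (std::size_t)j * n,
                 *cj = pc + (std::size_t)j * n, *rj = pr + (std::size_t)j * n;
    double *xj = px + (std::size_t)j * n;
    cp[0] = cj[0] / bj[0];
    rp[0] = rj[0] / bj[0];
    for (int i = 1; i < n; ++i) {
      double den = bj[i] - aj[i] * cp[i - 1];
      cp[i] = cj[i] / den;
      rp[i] = (rj[i] - aj[i] * rp[i - 1]) / den;
    }
    xj[n - 1] = rp[n - 1];
    for (int i = n - 2; i >= 0; --i) xj[i] = rp[i] - cp[i] * xj[i + 1];
  }
  return x;
}
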