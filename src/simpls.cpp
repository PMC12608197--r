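// SIMPLS kernel (de Jong 1993) for univariate y, plus a cross-validation
// driver. Everything here is deterministic: fold assignments are computed in
// R and passed down, no RNG is touched on the C++ side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Coefficient paths B(:, a) for a = 1..A components on already-centered data.
// If the deflated covariance collapses before A components (rank deficiency),
// remaining columns repeat the last valid solution.
static mat simpls_B(const mat& Xc, const vec& yc, const int A) {
  const uword p = Xc.n_cols;
  vec s = Xc.t() * yc;
  const double s0 = norm(s);
  mat R(p, A, fill::zeros), V(p, A, fill::zeros), B(p, A, fill::zeros);
  vec q(A, fill::zeros);
  int used = 0;
  for (int a = 0; a < A; ++a) {
    vec r = s;
    if (norm(r) <= 1e-12 * std::max(1.0, s0)) break;
    vec t = Xc * r;
    const double tn = norm(t);
    if (tn <= 1e-12) break;
    t /= tn; r /= tn;
    vec pl = Xc.t() * t;
    const double qa = dot(yc, t);
    vec v = pl;
    if (a > 0) {
      const mat Vp = V.cols(0, a - 1);
      v -= Vp * (Vp.t() * pl);
    }
    const double vn = norm(v);
    if (vn <= 1e-12) break;
    v /= vn;
    s -= v * dot(v, s);
    R.col(a) = r; V.col(a) = v; q(a) = qa;
    B.col(a) = R.cols(0, a) * q.subvec(0, a);
    used = a + 1;
  }
  for (int a = used; a < A; ++a)
    B.col(a) = (used > 0) ? B.col(used - 1) : vec(p, fill::zeros);
  return B;
}

// [[Rcpp::export(name = ".simpls_path")]]
Rcpp::List simpls_path(const arma::mat& X, const arma::vec& y, const int ncomp) {
  const rowvec xm = mean(X, 0);
  const double ym = mean(y);
  mat Xc = X;
  Xc.each_row() -= xm;
  const vec yc = y - ym;
  const mat B = simpls_B(Xc, yc, ncomp);
  return Rcpp::List::create(Rcpp::Named("B") = B,
                            Rcpp::Named("x_mean") = xm.t(),
                            Rcpp::Named("y_mean") = ym);
}

// Per-component RMSE of cross-validation. fold is 1-based fold id per row.
// [[Rcpp::export(name = ".cv_rmse_path")]]
arma::vec cv_rmse_path(const arma::mat& X, const arma::vec& y,
                       const arma::ivec& fold, const int ncomp) {
  const int F = fold.max();
  vec sse(ncomp, fill::zeros);
  for (int f = 1; f <= F; ++f) {
    const uvec te = find(fold == f);
    const uvec tr = find(fold != f);
    mat Xtr = X.rows(tr);
    const rowvec xm = mean(Xtr, 0);
    const double ym = mean(y(tr));
    Xtr.each_row() -= xm;
    const mat B = simpls_B(Xtr, y(tr) - ym, ncomp);
    mat Xte = X.rows(te);
    Xte.each_row() -= xm;
    for (int a = 0; a < ncomp; ++a) {
      const vec e = y(te) - (ym + Xte * B.col(a));
      sse(a) += dot(e, e);
    }
  }
  return sqrt(sse / (double) X.n_rows);
}
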