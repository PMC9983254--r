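// Batch exact four-point sphere solves.
//
// For each quadruple of indices the 4x4 system
//   [1 x_i y_i z_i] . [p1 p2 p3 p4]^T = -(x_i^2 + y_i^2 + z_i^2)
// is solved exactly; back-substitution gives centre (-p2/2, -p3/2, -p4/2)
// and radius sqrt(xm^2 + ym^2 + zm^2 - p1). Degenerate (coplanar) quadruples
// and fits with R^2 <= 0 are flagged invalid, never thrown: combination
// sweeps over tens of thousands of quadruples must not abort.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".fit_quadruples")]]
Rcpp::NumericMatrix fit_quadruples(const arma::mat& pts,
                                   const arma::imat& combos) {
  const arma::uword m = combos.n_rows;
  Rcpp::NumericMatrix out(m, 5); // xm, ym, zm, R, valid
  arma::mat K(4, 4);
  arma::vec b(4), p(4);
  for (arma::uword k = 0; k < m; ++k) {
    for (arma::uword j = 0; j < 4; ++j) {
      const arma::uword i = static_cast<arma::uword>(combos(k, j)) - 1;
      K(j, 0) = 1.0;
      K(j, 1) = pts(i, 0);
      K(j, 2) = pts(i, 1);
      K(j, 3) = pts(i, 2);
      b(j) = -(pts(i, 0) * pts(i, 0) + pts(i, 1) * pts(i, 1) +
               pts(i, 2) * pts(i, 2));
    }
    bool ok = arma::solve(p, K, b, arma::solve_opts::no_approx);
    double xm = 0, ym = 0, zm = 0, R = 0;
    if (ok) {
      xm = -p(1) / 2.0;
      ym = -p(2) / 2.0;
      zm = -p(3) / 2.0;
      const double r2 = xm * xm + ym * ym + zm * zm - p(0);
      if (r2 > 0.0 && std::isfinite(r2)) {
        R = std::sqrt(r2);
      } else {
        ok = false;
      }
      if (!(std::isfinite(xm) && std::isfinite(ym) && std::isfinite(zm)))
        ok = false;
    }
    out(k, 0) = xm;
    out(k, 1) = ym;
    out(k, 2) = zm;
    out(k, 3) = R;
    out(k, 4) = ok ? 1.0 : 0.0;
  }
  return out;
}
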