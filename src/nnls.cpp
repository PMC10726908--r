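#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Lawson-Hanson active-set non-negative least squares:
// minimize ||A x - b||^2 subject to x >= 0.
// Returns the exact minimizer (KKT point) up to the dual tolerance.
//' @noRd
// [[Rcpp::export(name = ".nnls_cpp")]]
arma::vec nnls_cpp(const arma::mat& A, const arma::vec& b, double tol_rel) {
  const arma::uword n = A.n_cols;
  arma::vec x(n, arma::fill::zeros);
  std::vector<bool> inP(n, false);
  arma::vec w = A.t() * b;  // negative gradient at x = 0

  const double scale = std::max(arma::norm(w, "inf"), 1.0);
  const double tol = tol_rel * scale;
  const int maxit = 10 * static_cast<int>(n) + 50;
  int outer = 0;

  while (outer++ < maxit) {
    // most violating coordinate in the zero set
    int j = -1;
    double wmax = tol;
    for (arma::uword i = 0; i < n; ++i) {
      if (!inP[i] && w[i] > wmax) { wmax = w[i]; j = static_cast<int>(i); }
    }
    if (j < 0) break;  // dual feasible: KKT satisfied
    inP[j] = true;

    int inner = 0;
    while (inner++ < maxit) {
      arma::uvec Pidx(n);
      arma::uword np = 0;
      for (arma::uword i = 0; i < n; ++i) if (inP[i]) Pidx[np++] = i;
      Pidx.resize(np);

      arma::vec zP;
      const bool ok = arma::solve(zP, A.cols(Pidx), b,
                                  arma::solve_opts::no_approx);
      if (!ok) {
        // rank-deficient passive set: drop the entering variable
        inP[j] = false;
        break;
      }
      if (zP.min() > 0.0) {
        x.zeros();
        x(Pidx) = zP;
        break;
      }
      // step toward zP, stopping at the first coordinate hitting zero
      double alpha = arma::datum::inf;
      for (arma::uword k = 0; k < np; ++k) {
        if (zP[k] <= 0.0) {
          const double xi = x[Pidx[k]];
          const double a = xi / (xi - zP[k]);
          if (a < alpha) alpha = a;
        }
      }
      for (arma::uword k = 0; k < np; ++k) {
        x[Pidx[k]] += alpha * (zP[k] - x[Pidx[k]]);
      }
      for (arma::uword k = 0; k < np; ++k) {
        if (zP[k] <= 0.0 && x[Pidx[k]] <= scale * 1e-14) {
          x[Pidx[k]] = 0.0;
          inP[Pidx[k]] = false;
        }
      }
    }
    w = A.t() * (b - A * x);
  }
  return x;
}
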