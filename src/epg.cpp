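#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// CPMG extended phase graph recursion with real-valued configuration states.
//
// Phase convention: 90 deg excitation about y, refocusing pulses about x,
// so all F states stay real (CPMG condition).  States are stored as
//   a[k] = F_{+k},  b[k] = F_{-k},  z[k] = Z_k,   k = 0..K
// with the conjugate-symmetry constraint b[0] == a[0] and z[0] == 0
// (longitudinal recovery is omitted: echo amplitudes only).
//
// Per echo interval: relax tau = esp/2, dephase (+1 shift), refocusing
// rotation, relax tau, dephase; the k = 0 transverse state is the echo.
// Relaxation scales all F states uniformly so it commutes with the shift.
static void epg_echoes(double t2, double alpha_deg, int n_echoes,
                       double esp, double t1, double* out) {
  const int K = n_echoes + 1;  // state order beyond echo count: no truncation
  arma::vec a(K + 1, arma::fill::zeros);
  arma::vec b(K + 1, arma::fill::zeros);
  arma::vec z(K + 1, arma::fill::zeros);
  a[0] = 1.0;  // after ideal 90 deg excitation
  b[0] = 1.0;

  const double tau = esp / 2.0;
  const double E2 = std::exp(-tau / t2);
  const double E1 = std::exp(-tau / t1);
  const double half = alpha_deg * M_PI / 360.0;
  const double c2 = std::cos(half) * std::cos(half);
  const double s2 = std::sin(half) * std::sin(half);
  const double sa = std::sin(2.0 * half);
  const double ca = std::cos(2.0 * half);

  for (int e = 0; e < n_echoes; ++e) {
    // two half-intervals per echo, pulse in between
    for (int halfstep = 0; halfstep < 2; ++halfstep) {
      a.head(K + 1) *= E2;
      b.head(K + 1) *= E2;
      z.head(K + 1) *= E1;
      // dephasing shift F_k -> F_{k+1}
      for (int k = K; k >= 1; --k) a[k] = a[k - 1];
      a[0] = b[1];
      for (int k = 0; k < K; ++k) b[k] = b[k + 1];
      b[K] = 0.0;
      b[0] = a[0];

      if (halfstep == 0) {
        // refocusing rotation; k = 0 has z[0] == 0 and b[0] == a[0], so it
        // is invariant and needs no update
        for (int k = 1; k <= K; ++k) {
          const double ak = a[k], bk = b[k], zk = z[k];
          a[k] = c2 * ak + s2 * bk + sa * zk;
          b[k] = s2 * ak + c2 * bk - sa * zk;
          z[k] = -0.5 * sa * ak + 0.5 * sa * bk + ca * zk;
        }
      }
    }
    out[e] = std::abs(a[0]);  // k = 0 transverse state magnitude
  }
}

//' @noRd
// [[Rcpp::export(name = ".epg_cpmg_cpp")]]
arma::vec epg_cpmg_cpp(double t2, double alpha_deg, int n_echoes,
                       double esp, double t1) {
  arma::vec out(n_echoes);
  epg_echoes(t2, alpha_deg, n_echoes, esp, t1, out.memptr());
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".epg_basis_cpp")]]
arma::mat epg_basis_cpp(const arma::vec& t2_values, double alpha_deg,
                        int n_echoes, double esp, double t1) {
  arma::mat basis(n_echoes, t2_values.n_elem);
  for (arma::uword j = 0; j < t2_values.n_elem; ++j) {
    epg_echoes(t2_values[j], alpha_deg, n_echoes, esp, t1, basis.colptr(j));
  }
  return basis;
}
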