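// Frequency-domain TQWT analysis/synthesis cascade.
//
// The R level decides padding and per-level subband lengths; here we only
// execute the DFT-domain filter bank. Unitary DFT normalization per
// subband makes the transform a Parseval frame, so synthesis is the
// adjoint of analysis and reconstruction is exact.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Daubechies-type transition samples theta(i*pi/(tb+1)), i = 1..tb
static vec theta_vec(const int tb) {
  vec v(tb > 0 ? tb : 0);
  for (int i = 0; i < tb; ++i) {
    double w = (i + 1) * M_PI / (tb + 1);
    v[i] = 0.5 * (1.0 + std::cos(w)) * std::sqrt(2.0 - std::cos(w));
  }
  return v;
}

// [[Rcpp::export(name = ".tqwt_fwd_cpp")]]
Rcpp::List tqwt_fwd_cpp(const arma::vec& xp,
                        const arma::ivec& n0s,
                        const arma::ivec& n1s) {
  const int J = n0s.n_elem;
  cx_vec X = fft(xp) / std::sqrt(static_cast<double>(xp.n_elem));
  Rcpp::List out(J + 1);
  for (int j = 0; j < J; ++j) {
    const int n = X.n_elem;
    const int n0 = n0s[j], n1 = n1s[j];
    const int p = (n - n1) / 2;
    const int tb = (n0 + n1 - n) / 2 - 1;
    const vec tr = theta_vec(tb);
    cx_vec V0(n0, fill::zeros), V1(n1, fill::zeros);

    V0[0] = X[0];
    for (int k = 1; k <= p; ++k) {
      V0[k] = X[k];
      V0[n0 - k] = X[n - k];
    }
    for (int i = 0; i < tb; ++i) {
      V0[p + 1 + i]       = X[p + 1 + i] * tr[i];
      V1[1 + i]           = X[p + 1 + i] * tr[tb - 1 - i];
      V0[n0 - p - tb + i] = X[n - p - tb + i] * tr[tb - 1 - i];
      V1[n1 - tb + i]     = X[n - p - tb + i] * tr[i];
    }
    for (int k = tb + 1; k < n1 / 2; ++k) V1[k] = X[p + k];
    V1[n1 / 2] = X[n / 2];
    for (int k = n1 / 2 + 1; k < n1 - tb; ++k) V1[k] = X[k + (n - n1) / 2];

    out[j] = Rcpp::wrap(real(ifft(V1)) * std::sqrt(static_cast<double>(n1)));
    X = V0;  // low-pass output feeds the next stage
  }
  const int nJ = X.n_elem;
  out[J] = Rcpp::wrap(real(ifft(X)) * std::sqrt(static_cast<double>(nJ)));
  return out;
}

// [[Rcpp::export(name = ".tqwt_inv_cpp")]]
arma::vec tqwt_inv_cpp(const Rcpp::List& subbands,
                       const int np,
                       const arma::ivec& n0s,
                       const arma::ivec& n1s) {
  const int J = n0s.n_elem;
  vec low = Rcpp::as<vec>(subbands[J]);
  cx_vec Y = fft(low) / std::sqrt(static_cast<double>(low.n_elem));
  for (int j = J - 1; j >= 0; --j) {
    const int n = (j == 0) ? np : n0s[j - 1];
    const int n0 = n0s[j], n1 = n1s[j];
    const int p = (n - n1) / 2;
    const int tb = (n0 + n1 - n) / 2 - 1;
    const vec tr = theta_vec(tb);
    vec hp = Rcpp::as<vec>(subbands[j]);
    cx_vec W = fft(hp) / std::sqrt(static_cast<double>(n1));
    cx_vec Yp(n, fill::zeros);

    Yp[0] = Y[0];
    for (int k = 1; k <= p; ++k) {
      Yp[k] = Y[k];
      Yp[n - k] = Y[n0 - k];
    }
    for (int i = 0; i < tb; ++i) {
      Yp[p + 1 + i]       = Y[p + 1 + i] * tr[i] + W[1 + i] * tr[tb - 1 - i];
      Yp[n - p - tb + i]  = Y[n0 - p - tb + i] * tr[tb - 1 - i] + W[n1 - tb + i] * tr[i];
    }
    for (int k = tb + 1; k < n1 / 2; ++k) Yp[p + k] = W[k];
    Yp[n / 2] = W[n1 / 2];
    for (int k = n1 / 2 + 1; k < n1 - tb; ++k) Yp[k + (n - n1) / 2] = W[k];

    Y = Yp;
  }
  return real(ifft(Y)) * std::sqrt(static_cast<double>(np));
}
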