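#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// One biquad, direct form II transposed, with externally supplied initial
// state (z1, z2).  In-place over a std::vector.
static void biquad_apply(std::vector<double> &x,
                         double b0, double b1, double b2,
                         double a1, double a2,
                         double z1, double z2) {
  const size_t n = x.size();
  for (size_t t = 0; t < n; ++t) {
    const double xt = x[t];
    const double yt = b0 * xt + z1;
    z1 = b1 * xt - a1 * yt + z2;
    z2 = b2 * xt - a2 * yt;
    x[t] = yt;
  }
}

// Steady-state unit-step filter state; scaled by the first sample so the
// filter starts at its step-response equilibrium (suppresses start-up
// transients, essential for the 0.1 Hz high-pass).
static inline void steady_state_zi(double b0, double b1, double b2,
                                   double a1, double a2,
                                   double &z1, double &z2) {
  const double K = (b0 + b1 + b2) / (1.0 + a1 + a2);
  z1 = K - b0;
  z2 = b2 - a2 * K;
}

// Forward-backward (zero-phase) cascade of biquads over each column of x.
// sos: n_sections x 6 matrix, rows (b0, b1, b2, 1, a1, a2).
// Columns are extended by odd reflection of length padlen before filtering.
// [[Rcpp::export]]
NumericMatrix sosfiltfilt_mat(const NumericMatrix &x,
                              const NumericMatrix &sos,
                              int padlen) {
  const int n = x.nrow(), nc = x.ncol(), ns = sos.nrow();
  if (sos.ncol() != 6) stop("sos must have 6 columns");
  if (n < 2) stop("need at least 2 samples");
  const int pad = std::min(padlen, n - 1);

  NumericMatrix out(n, nc);
  std::vector<double> ext;
  for (int c = 0; c < nc; ++c) {
    ext.assign(n + 2 * pad, 0.0);
    // odd (anti-symmetric) reflection about the end points
    for (int t = 0; t < pad; ++t)
      ext[t] = 2.0 * x(0, c) - x(pad - t, c);
    for (int t = 0; t < n; ++t)
      ext[pad + t] = x(t, c);
    for (int t = 0; t < pad; ++t)
      ext[pad + n + t] = 2.0 * x(n - 1, c) - x(n - 2 - t, c);

    for (int pass = 0; pass < 2; ++pass) {
      for (int s = 0; s < ns; ++s) {
        const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
        const double a1 = sos(s, 4), a2 = sos(s, 5);
        double z1, z2;
        steady_state_zi(b0, b1, b2, a1, a2, z1, z2);
        biquad_apply(ext, b0, b1, b2, a1, a2,
                     z1 * ext.front(), z2 * ext.front());
      }
      std::reverse(ext.begin(), ext.end());
    }
    for (int t = 0; t < n; ++t) out(t, c) = ext[pad + t];
  }
  return out;
}
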