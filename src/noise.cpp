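#include <Rcpp.h>
using namespace Rcpp;

// Hermitian half-spectrum of independent complex-Gaussian coefficients
// with per-bin amplitudes amp[k-1] for bins k = 1..length(amp); bin 0 (DC)
// and, for even n, the Nyquist bin get nyq_amp * N(0,1) (real).  The
// inverse FFT of a column is then a real Gaussian series with power
// spectrum proportional to amp^2.  Uses R's RNG (draw order: per channel,
// bin-major), so results are reproducible from set.seed().
// [[Rcpp::export]]
ComplexMatrix noise_half_spectrum(int n, int nch, NumericVector amp,
                                  double nyq_amp) {
  const int nh = amp.size();
  if (2 * nh >= n + 1) stop("too many half-spectrum bins");
  ComplexMatrix F(n, nch);
  GetRNGstate();
  for (int c = 0; c < nch; ++c) {
    for (int k = 1; k <= nh; ++k) {
      const double re = norm_rand() * amp[k - 1];
      const double im = norm_rand() * amp[k - 1];
      F(k, c).r = re;       F(k, c).i = im;
      F(n - k, c).r = re;   F(n - k, c).i = -im;
    }
    if (n % 2 == 0) {
      F(n / 2, c).r = norm_rand() * nyq_amp;
      F(n / 2, c).i = 0.0;
    }
  }
  PutRNGstate();
  return F;
}
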