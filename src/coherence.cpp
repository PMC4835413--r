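// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Welch magnitude-squared coherence of every channel pair, averaged over
// the frequency bins lo <= f <= hi, returned on the correlation-like scale
// sqrt(mean MSC).  x: n_samples x n_channels; nper: samples per segment;
// step: hop between segment starts (nper * (1 - overlap)).  Segments are
// Hann-tapered and zero-padded to the next power of two for the FFT.
// Channels with zero spectral power get zero rows/columns.
// [[Rcpp::export]]
arma::mat welch_band_coherence(const arma::mat &x, double fs, int nper,
                               int step, double lo, double hi) {
  const int n = x.n_rows, nch = x.n_cols;
  if (nper < 4 || nper > n) Rcpp::stop("segment length out of range");
  if (step < 1) Rcpp::stop("step must be >= 1");
  const int nseg = (n - nper) / step + 1;

  int nfft = 1;
  while (nfft < nper) nfft <<= 1;

  // Hann taper
  arma::vec win(nper);
  for (int t = 0; t < nper; ++t)
    win[t] = 0.5 * (1.0 - std::cos(2.0 * M_PI * t / (nper - 1)));

  // in-band rfft bins
  std::vector<int> bins;
  for (int k = 0; k <= nfft / 2; ++k) {
    const double f = k * fs / nfft;
    if (f >= lo && f <= hi) bins.push_back(k);
  }
  const int nbin = static_cast<int>(bins.size());
  if (nbin == 0)
    Rcpp::stop("no frequency bins inside [%g, %g] Hz at resolution %g Hz",
               lo, hi, fs / nfft);

  // segment spectra gathered per bin: C(seg, ch, bin)
  arma::cx_cube C(nseg, nch, nbin, arma::fill::zeros);
  arma::mat seg(nfft, nch, arma::fill::zeros);
  for (int s = 0; s < nseg; ++s) {
    seg.rows(0, nper - 1) = x.rows(s * step, s * step + nper - 1);
    seg.rows(0, nper - 1).each_col() %= win;
    arma::cx_mat F = arma::fft(seg);             // nfft x nch
    for (int b = 0; b < nbin; ++b)
      C.slice(b).row(s) = F.row(bins[b]);
  }

  arma::mat coh2(nch, nch, arma::fill::zeros);
  for (int b = 0; b < nbin; ++b) {
    const arma::cx_mat S = arma::trans(C.slice(b)) * C.slice(b);
    const arma::vec d = arma::real(S.diag());
    for (int i = 0; i < nch; ++i) {
      for (int j = 0; j < nch; ++j) {
        const double den = d[i] * d[j];
        if (den > 0.0) coh2(i, j) += std::norm(S(i, j)) / den;
      }
    }
  }
  coh2 /= nbin;
  arma::mat coh = arma::sqrt(coh2);
  coh.diag().zeros();
  return coh;
}
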