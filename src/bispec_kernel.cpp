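#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

// Segment-averaged bispectrum accumulation on the first quadrant.
//
// X: nfft x nseg complex matrix of per-segment FFTs (windowed, detrended).
// K: Nyquist bin index (nfft / 2).
//
// Returns a list with:
//   mean:     (K+1) x (K+1) complex matrix, mean over segments of
//             X(k1) * X(k2) * conj(X(k1 + k2)) for k1 + k2 <= K, 0 elsewhere.
//   mean_abs: (K+1) x (K+1) real matrix, mean over segments of the
//             magnitude of the same triple product (incoherent level,
//             used for phase-coherence diagnostics).
//
// The quadrant is symmetric in (k1, k2); only k1 <= k2 is computed and
// the result is mirrored.
// [[Rcpp::export]]
List bispec_accumulate(const ComplexMatrix& X, const int K) {
  const int nseg = X.ncol();
  const int n = K + 1;
  std::vector< std::complex<double> > acc((size_t)n * n, std::complex<double>(0.0, 0.0));
  std::vector<double> acc_abs((size_t)n * n, 0.0);

  for (int s = 0; s < nseg; ++s) {
    std::vector< std::complex<double> > x(X.nrow());
    for (int i = 0; i < X.nrow(); ++i) {
      Rcomplex z = X(i, s);
      x[i] = std::complex<double>(z.r, z.i);
    }
    for (int k2 = 0; k2 <= K; ++k2) {
      const std::complex<double> x2 = x[k2];
      const int k1max = std::min(k2, K - k2);
      for (int k1 = 0; k1 <= k1max; ++k1) {
        const std::complex<double> t = x[k1] * x2 * std::conj(x[k1 + k2]);
        acc[(size_t)k2 * n + k1] += t;
        acc_abs[(size_t)k2 * n + k1] += std::abs(t);
      }
    }
  }

  ComplexMatrix Bm(n, n);
  NumericMatrix Ba(n, n);
  const double inv = 1.0 / (double)nseg;
  for (int k2 = 0; k2 <= K; ++k2) {
    for (int k1 = 0; k1 <= K; ++k1) {
      // stored value lives at (min, max); bins outside the support
      // f1 + f2 <= f_N stay zero
      std::complex<double> v(0.0, 0.0);
      double va = 0.0;
      if (k1 + k2 <= K) {
        const int a = std::min(k1, k2), b = std::max(k1, k2);
        v = acc[(size_t)b * n + a] * inv;
        va = acc_abs[(size_t)b * n + a] * inv;
      }
      Rcomplex z; z.r = v.real(); z.i = v.imag();
      Bm(k1, k2) = z;
      Ba(k1, k2) = va;
    }
  }
  return List::create(_["mean"] = Bm, _["mean_abs"] = Ba);
}
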