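#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Steered-response power over a grid of candidate source nodes.
//
// S    : nfreq x nmic complex spectra of the per-channel snippets
// freqs: nfreq frequencies (Hz)
// tau  : nnode x nmic propagation delays (s) from each node to each mic
//
// value per node: sum_f | sum_m S(f,m) * exp(+i 2 pi f tau(node,m)) |^2
// The +i steering phase conjugate-cancels the -i propagation phase of a
// source located at the node, so in-phase summation peaks at the origin.
// [[Rcpp::export]]
NumericVector dso_scan(const ComplexMatrix& S,
                       const NumericVector& freqs,
                       const NumericMatrix& tau) {
  const int nfreq = S.nrow(), nmic = S.ncol(), nnode = tau.nrow();
  if (freqs.size() != nfreq) stop("freqs length must match nrow(S)");
  if (tau.ncol() != nmic) stop("ncol(tau) must match ncol(S)");
  NumericVector out(nnode);
  const double twopi = 2.0 * M_PI;
  for (int g = 0; g < nnode; ++g) {
    double acc = 0.0;
    for (int f = 0; f < nfreq; ++f) {
      const double w = twopi * freqs[f];
      double re = 0.0, im = 0.0;
      for (int m = 0; m < nmic; ++m) {
        const double ph = w * tau(g, m);
        const double c = std::cos(ph), s = std::sin(ph);
        const Rcomplex sm = S(f, m);
        // (sm.r + i sm.i) * (c + i s)
        re += sm.r * c - sm.i * s;
        im += sm.r * s + sm.i * c;
      }
      acc += re * re + im * im;
    }
    out[g] = acc;
  }
  return out;
}
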