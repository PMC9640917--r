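// Affine (rotation/scale/flip) bilinear warp of a square patch about its
// centre, used by the augmentation pipeline.  Border-clamped sampling.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".warp_affine")]]
NumericMatrix warp_affine(NumericMatrix img, double theta, double scale,
                          bool flip_h, bool flip_v) {
  const int S = img.nrow();
  if (img.ncol() != S) stop("warp_affine: patch must be square");
  const double ctr = (S + 1.0) / 2.0;
  const double co = std::cos(-theta), si = std::sin(-theta);
  NumericMatrix out(S, S);
  for (int c = 0; c < S; ++c) {
    double gc = (c + 1.0) - ctr;
    if (flip_h) gc = -gc;
    for (int r = 0; r < S; ++r) {
      double gr = (r + 1.0) - ctr;
      if (flip_v) gr = -gr;
      double sr = (co * gr - si * gc) / scale + ctr;
      double sc = (si * gr + co * gc) / scale + ctr;
      sr = std::min(std::max(sr, 1.0), (double)S);
      sc = std::min(std::max(sc, 1.0), (double)S);
      int r0 = std::min((int)std::floor(sr), S - 1);
      int c0 = std::min((int)std::floor(sc), S - 1);
      double fr = sr - r0, fc = sc - c0;
      int r1 = std::min(r0 + 1, S), c1 = std::min(c0 + 1, S);
      // r0/c0 are 1-based sample coords; convert to 0-based indices
      double v = img(r0 - 1, c0 - 1) * (1 - fr) * (1 - fc) +
                 img(r1 - 1, c0 - 1) * fr * (1 - fc) +
                 img(r0 - 1, c1 - 1) * (1 - fr) * fc +
                 img(r1 - 1, c1 - 1) * fr * fc;
      out(r, c) = v;
    }
  }
  return out;
}
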