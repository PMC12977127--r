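#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Generalized winding number of a triangle mesh at arbitrary points.
// Per-triangle signed solid angle via the Van Oosterom & Strackee formula:
//   Omega = 2 * atan2(det[a b c], |a||b||c| + (a.b)|c| + (b.c)|a| + (c.a)|b|)
// with a, b, c the triangle vertices relative to the query point.
// Returns the summed solid angle divided by 4*pi (~1 inside, ~0 outside a
// closed, consistently outward-oriented surface).

// [[Rcpp::export]]
NumericVector cpp_winding_number(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix P) {
  const int nf = F.nrow(), np = P.nrow();
  // triangle vertex coordinates packed contiguously for cache locality
  std::vector<double> t(static_cast<size_t>(nf) * 9);
  for (int f = 0; f < nf; ++f) {
    for (int c = 0; c < 3; ++c) {
      const int v = F(f, c);  // 0-based
      t[f * 9 + c * 3 + 0] = V(v, 0);
      t[f * 9 + c * 3 + 1] = V(v, 1);
      t[f * 9 + c * 3 + 2] = V(v, 2);
    }
  }
  NumericVector w(np);
  for (int i = 0; i < np; ++i) {
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
    const double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    double acc = 0.0;
    const double* tp = t.data();
    for (int f = 0; f < nf; ++f, tp += 9) {
      const double ax = tp[0] - px, ay = tp[1] - py, az = tp[2] - pz;
      const double bx = tp[3] - px, by = tp[4] - py, bz = tp[5] - pz;
      const double cx = tp[6] - px, cy = tp[7] - py, cz = tp[8] - pz;
      const double la = std::sqrt(ax * ax + ay * ay + az * az);
      const double lb = std::sqrt(bx * bx + by * by + bz * bz);
      const double lc = std::sqrt(cx * cx + cy * cy + cz * cz);
      const double det = ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) +
                         az * (bx * cy - by * cx);
      const double denom = la * lb * lc + (ax * bx + ay * by + az * bz) * lc +
                           (bx * cx + by * cy + bz * cz) * la +
                           (cx * ax + cy * ay + cz * az) * lb;
      acc += 2.0 * std::atan2(det, denom);
    }
    w[i] = acc / (4.0 * M_PI);
  }
  return w;
}
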