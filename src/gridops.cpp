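#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <unordered_set>
using namespace Rcpp;

// Voxel-grid label operations shared by the volumetric atlas pipeline.
// All arrays are 3-D, column-major (R layout), indices 0-based internally.

static void neighbor_offsets(int connectivity, std::vector<int>& dx,
                             std::vector<int>& dy, std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        const int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2))
          continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// Synchronized competitive label expansion: per iteration, every voxel whose
// label is in `targets` (and not protected) that touches >= 1 voxel whose
// label is in `sources` adopts the smallest such neighboring label.
// [[Rcpp::export]]
IntegerVector cpp_expand_labels(IntegerVector vol, IntegerVector dim,
                                int iterations, IntegerVector sources,
                                IntegerVector targets, int connectivity,
                                LogicalVector protect) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  std::unordered_set<int> src(sources.begin(), sources.end());
  std::unordered_set<int> tgt(targets.begin(), targets.end());
  const bool has_protect = protect.size() == vol.size();
  IntegerVector cur = clone(vol);
  IntegerVector nxt(vol.size());
  for (int it = 0; it < iterations; ++it) {
    Rcpp::checkUserInterrupt();
    std::copy(cur.begin(), cur.end(), nxt.begin());
    bool changed = false;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const R_xlen_t idx =
              (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          if (!tgt.count(cur[idx])) continue;
          if (has_protect && protect[idx]) continue;
          int best = NA_INTEGER;
          for (size_t k = 0; k < dx.size(); ++k) {
            const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            const int lab =
                cur[(R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
            if (src.count(lab) && (best == NA_INTEGER || lab < best))
              best = lab;
          }
          if (best != NA_INTEGER) { nxt[idx] = best; changed = true; }
        }
    std::copy(nxt.begin(), nxt.end(), cur.begin());
    if (!changed) break;
  }
  return cur;
}

// Synchronized neighborhood-mode filter (center included). Tie rule: keep the
// current label if it ties for the mode, otherwise the smallest tied label.
// [[Rcpp::export]]
IntegerVector cpp_mode_filter_volume(IntegerVector vol, IntegerVector dim,
                                     int iterations, int connectivity,
                                     LogicalVector frozen, bool ignore_zero) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  const bool has_frozen = frozen.size() == vol.size();
  IntegerVector cur = clone(vol);
  IntegerVector nxt(vol.size());
  std::vector<int> labs(28), cnts(28);
  for (int it = 0; it < iterations; ++it) {
    Rcpp::checkUserInterrupt();
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const R_xlen_t idx =
              (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          const int self = cur[idx];
          if (has_frozen && frozen[idx]) { nxt[idx] = self; continue; }
          if (ignore_zero && self == 0) { nxt[idx] = 0; continue; }
          int nlab = 0;
          labs[nlab] = self; cnts[nlab++] = 1;
          for (size_t k = 0; k < dx.size(); ++k) {
            const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            const int lab =
                cur[(R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
            if (ignore_zero && lab == 0) continue;
            int j = 0;
            for (; j < nlab; ++j)
              if (labs[j] == lab) { ++cnts[j]; break; }
            if (j == nlab) { labs[nlab] = lab; cnts[nlab++] = 1; }
          }
          int bestc = -1, best = self;
          for (int j = 0; j < nlab; ++j) {
            if (cnts[j] > bestc ||
                (cnts[j] == bestc &&
                 (labs[j] == self || (best != self && labs[j] < best)))) {
              bestc = cnts[j]; best = labs[j];
            }
          }
          nxt[idx] = best;
        }
    std::copy(nxt.begin(), nxt.end(), cur.begin());
  }
  return cur;
}

// Connected components of a logical mask (6-connectivity). 0 outside the
// mask, components numbered 1..K in scan order.
// [[Rcpp::export]]
IntegerVector cpp_connected_components3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  int comp = 0;
  std::vector<R_xlen_t> stack;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || lab[s]) continue;
    ++comp;
    stack.push_back(s);
    lab[s] = comp;
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      for (int k = 0; k < 6; ++k) {
        const int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        const R_xlen_t w =
            (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && !lab[w]) { lab[w] = comp; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// Separable Gaussian blur with per-axis sigma in voxel units. Kernels are
// renormalized at the edges so constant images stay constant and the output
// range never exceeds the input range.
static void blur_axis(std::vector<double>& a, std::vector<double>& b, int nx,
                      int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) return;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  for (int i = -r; i <= r; ++i)
    k[i + r] = std::exp(-0.5 * (i * i) / (sigma * sigma));
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int len = n[axis];
  const R_xlen_t st = stride[axis];
  for (int z = 0; z < (axis == 2 ? 1 : nz); ++z)
    for (int y = 0; y < (axis == 1 ? 1 : ny); ++y)
      for (int x = 0; x < (axis == 0 ? 1 : nx); ++x) {
        const R_xlen_t base =
            (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int i = 0; i < len; ++i) {
          double s = 0.0, wsum = 0.0;
          const int lo = std::max(0, i - r), hi = std::min(len - 1, i + r);
          for (int j = lo; j <= hi; ++j) {
            const double wk = k[j - i + r];
            s += wk * a[base + (R_xlen_t)j * st];
            wsum += wk;
          }
          b[base + (R_xlen_t)i * st] = s / wsum;
        }
      }
  a.swap(b);
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3d(NumericVector vol, IntegerVector dim,
                                  NumericVector sigma_voxels) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end()), b(vol.size());
  blur_axis(a, b, nx, ny, nz, 0, sigma_voxels[0]);
  blur_axis(a, b, nx, ny, nz, 1, sigma_voxels[1]);
  blur_axis(a, b, nx, ny, nz, 2, sigma_voxels[2]);
  NumericVector out(vol.size());
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Sample a 3-D volume at continuous 0-based voxel coordinates.
// method 0 = nearest neighbor, 1 = trilinear. Coordinates are clamped to the
// grid (nearest-edge extrapolation).
// [[Rcpp::export]]
NumericVector cpp_sample_volume(NumericVector vol, IntegerVector dim,
                                NumericMatrix pts, int method) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t np = pts.nrow();
  NumericVector out(np);
  for (R_xlen_t i = 0; i < np; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    x = std::min(std::max(x, 0.0), (double)(nx - 1));
    y = std::min(std::max(y, 0.0), (double)(ny - 1));
    z = std::min(std::max(z, 0.0), (double)(nz - 1));
    if (method == 0) {
      const int xi = (int)std::lround(x), yi = (int)std::lround(y),
                zi = (int)std::lround(z);
      out[i] = vol[(R_xlen_t)xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
    } else {
      const int x0 = std::min((int)std::floor(x), nx - 2 >= 0 ? nx - 2 : 0);
      const int y0 = std::min((int)std::floor(y), ny - 2 >= 0 ? ny - 2 : 0);
      const int z0 = std::min((int)std::floor(z), nz - 2 >= 0 ? nz - 2 : 0);
      const double fx = x - x0, fy = y - y0, fz = z - z0;
      double acc = 0.0;
      for (int c = 0; c < 8; ++c) {
        const int ox = c & 1, oy = (c >> 1) & 1, oz = (c >> 2) & 1;
        const int xi = std::min(x0 + ox, nx - 1);
        const int yi = std::min(y0 + oy, ny - 1);
        const int zi = std::min(z0 + oz, nz - 1);
        const double w = (ox ? fx : 1 - fx) * (oy ? fy : 1 - fy) *
                         (oz ? fz : 1 - fz);
        acc += w * vol[(R_xlen_t)xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)];
      }
      out[i] = acc;
    }
  }
  return out;
}
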