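// Mean intercept length by parallel test-line casting. For each direction a
// grid of parallel lines (spacing in voxel units, seeded in-plane offsets) is
// clipped against the ROI box; the binary volume is sampled at 0.5-voxel
// steps along each clipped segment and background->foreground transitions are
// counted. Lengths are returned in voxel units.
#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_mil_lines")]]
List cpp_mil_lines(IntegerVector data, IntegerVector dim, NumericMatrix dirs,
                   double spacing, NumericMatrix offsets) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  const int* bin = INTEGER(data);
  int nd = dirs.nrow();
  NumericVector total_len(nd);
  IntegerVector crossings(nd);
  double n3[3] = {(double)nx, (double)ny, (double)nz};
  double ctr[3] = {(nx - 1) / 2.0, (ny - 1) / 2.0, (nz - 1) / 2.0};

  for (int k = 0; k < nd; ++k) {
    double d[3] = {dirs(k, 0), dirs(k, 1), dirs(k, 2)};
    // orthonormal in-plane basis
    double ax[3] = {1.0, 0.0, 0.0};
    if (std::fabs(d[0]) > 0.9) { ax[0] = 0.0; ax[1] = 1.0; }
    double u[3] = {d[1] * ax[2] - d[2] * ax[1], d[2] * ax[0] - d[0] * ax[2],
                   d[0] * ax[1] - d[1] * ax[0]};
    double un = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    for (int j = 0; j < 3; ++j) u[j] /= un;
    double v[3] = {d[1] * u[2] - d[2] * u[1], d[2] * u[0] - d[0] * u[2],
                   d[0] * u[1] - d[1] * u[0]};
    // in-plane extent of the box corners relative to its center
    double amin = 0, amax = 0, bmin = 0, bmax = 0;
    for (int c = 0; c < 8; ++c) {
      double p[3];
      for (int j = 0; j < 3; ++j)
        p[j] = ((c >> j) & 1 ? n3[j] - 0.5 : -0.5) - ctr[j];
      double pa = p[0] * u[0] + p[1] * u[1] + p[2] * u[2];
      double pb = p[0] * v[0] + p[1] * v[1] + p[2] * v[2];
      amin = std::min(amin, pa); amax = std::max(amax, pa);
      bmin = std::min(bmin, pb); bmax = std::max(bmax, pb);
    }
    double len = 0.0;
    long cross = 0;
    for (double a = amin + offsets(k, 0); a <= amax; a += spacing)
      for (double b = bmin + offsets(k, 1); b <= bmax; b += spacing) {
        double o[3];
        for (int j = 0; j < 3; ++j) o[j] = ctr[j] + a * u[j] + b * v[j];
        // slab clipping against [-0.5, n-0.5]^3
        double tmin = -1e30, tmax = 1e30;
        bool miss = false;
        for (int j = 0; j < 3 && !miss; ++j) {
          double lo = -0.5, hi = n3[j] - 0.5;
          if (std::fabs(d[j]) < 1e-12) {
            if (o[j] < lo || o[j] > hi) miss = true;
          } else {
            double t1 = (lo - o[j]) / d[j], t2 = (hi - o[j]) / d[j];
            if (t1 > t2) std::swap(t1, t2);
            tmin = std::max(tmin, t1);
            tmax = std::min(tmax, t2);
          }
        }
        if (miss || tmax <= tmin) continue;
        len += tmax - tmin;
        int prev = -1;
        for (double t = tmin + 0.25; t <= tmax; t += 0.5) {
          int xi = (int)std::lround(o[0] + t * d[0]);
          int yi = (int)std::lround(o[1] + t * d[1]);
          int zi = (int)std::lround(o[2] + t * d[2]);
          if (xi < 0) xi = 0; else if (xi >= nx) xi = nx - 1;
          if (yi < 0) yi = 0; else if (yi >= ny) yi = ny - 1;
          if (zi < 0) zi = 0; else if (zi >= nz) zi = nz - 1;
          int val = bin[zi + (long)nz * (yi + (long)ny * xi)];
          if (prev == 0 && val == 1) ++cross;
          prev = val;
        }
      }
    total_len[k] = len;
    crossings[k] = (int)cross;
  }
  return List::create(_["total_length"] = total_len,
                      _["crossings"] = crossings);
}
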