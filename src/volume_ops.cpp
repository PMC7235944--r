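// Separable 3D filters and connected-component labeling for volumes stored as
// R arrays with dim = (nz, ny, nx), i.e. linear index z + nz*(y + ny*x).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // symmetric boundary (scipy "reflect"): -1 -> 0, -2 -> 1, n -> n-1, ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Convolve along one axis (stride, length) with a symmetric kernel.
static void conv_axis(std::vector<double>& a, int nz, int ny, int nx,
                      int axis, const std::vector<double>& k) {
  int R = ((int)k.size() - 1) / 2;
  int n[3] = {nz, ny, nx};
  long stride[3] = {1, (long)nz, (long)nz * ny};
  int L = n[axis];
  long s = stride[axis];
  // iterate over all lines along `axis`
  int oa1 = (axis + 1) % 3, oa2 = (axis + 2) % 3;
  std::vector<double> line(L);
  for (int i1 = 0; i1 < n[oa1]; ++i1) {
    for (int i2 = 0; i2 < n[oa2]; ++i2) {
      long base = (long)i1 * stride[oa1] + (long)i2 * stride[oa2];
      for (int i = 0; i < L; ++i) line[i] = a[base + (long)i * s];
      for (int i = 0; i < L; ++i) {
        double acc = 0.0;
        for (int j = -R; j <= R; ++j)
          acc += k[j + R] * line[reflect_idx(i + j, L)];
        a[base + (long)i * s] = acc;
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_gaussian_blur")]]
NumericVector cpp_gaussian_blur(NumericVector data, IntegerVector dim,
                                double sigma, int radius) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> a(data.begin(), data.end());
  std::vector<double> k(2 * radius + 1);
  double sum = 0.0;
  for (int j = -radius; j <= radius; ++j) {
    k[j + radius] = std::exp(-(double)j * j / (2.0 * sigma * sigma));
    sum += k[j + radius];
  }
  for (double& w : k) w /= sum;
  for (int axis = 0; axis < 3; ++axis) conv_axis(a, nz, ny, nx, axis, k);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Separable min (erode) or max (dilate) with a cube of side 2*radius+1.
// The ROI faces are artificial cut planes, so the border never constrains:
// erosion pads with foreground, dilation with background. Closing and
// opening are then identities on structures cut flat by an ROI face.
static void minmax_axis(std::vector<int>& a, int nz, int ny, int nx,
                        int axis, int R, bool take_max) {
  int n[3] = {nz, ny, nx};
  long stride[3] = {1, (long)nz, (long)nz * ny};
  int L = n[axis];
  long s = stride[axis];
  int oa1 = (axis + 1) % 3, oa2 = (axis + 2) % 3;
  std::vector<int> line(L);
  for (int i1 = 0; i1 < n[oa1]; ++i1) {
    for (int i2 = 0; i2 < n[oa2]; ++i2) {
      long base = (long)i1 * stride[oa1] + (long)i2 * stride[oa2];
      for (int i = 0; i < L; ++i) line[i] = a[base + (long)i * s];
      for (int i = 0; i < L; ++i) {
        int v = take_max ? 0 : 1;
        for (int j = -R; j <= R; ++j) {
          int ii = i + j;
          int x = (ii < 0 || ii >= L) ? (take_max ? 0 : 1) : line[ii];
          if (take_max) { if (x > v) v = x; } else { if (x < v) v = x; }
        }
        a[base + (long)i * s] = v;
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_morph")]]
IntegerVector cpp_morph(IntegerVector data, IntegerVector dim, int radius,
                        bool dilate) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> a(data.begin(), data.end());
  for (int axis = 0; axis < 3; ++axis)
    minmax_axis(a, nz, ny, nx, axis, radius, dilate);
  IntegerVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(IntegerVector data, IntegerVector dim,
                                   int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  long N = (long)nz * ny * nx;
  IntegerVector lab(N);
  lab.attr("dim") = dim;
  // neighbor offsets
  std::vector<int> dz, dy, dx;
  for (int ddx = -1; ddx <= 1; ++ddx)
    for (int ddy = -1; ddy <= 1; ++ddy)
      for (int ddz = -1; ddz <= 1; ++ddz) {
        int m = std::abs(ddx) + std::abs(ddy) + std::abs(ddz);
        if (m == 0) continue;
        if (connectivity == 6 && m != 1) continue;
        dz.push_back(ddz); dy.push_back(ddy); dx.push_back(ddx);
      }
  int nn = (int)dz.size();
  int next = 0;
  std::vector<long> stack;
  for (long i = 0; i < N; ++i) {
    if (data[i] == 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      long p = stack.back(); stack.pop_back();
      int z = (int)(p % nz);
      int y = (int)((p / nz) % ny);
      int x = (int)(p / ((long)nz * ny));
      for (int k = 0; k < nn; ++k) {
        int z2 = z + dz[k], y2 = y + dy[k], x2 = x + dx[k];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        long q = z2 + (long)nz * (y2 + (long)ny * x2);
        if (data[q] != 0 && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
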