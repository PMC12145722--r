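// Hot numeric kernels for the registration engine: trilinear sampling of
// 3D volumes at fractional voxel coordinates and separable Gaussian
// smoothing with replicated edges. Semantics match the R reference
// implementations in utils-array.R (which remain the documentation of
// record for edge handling).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// [[Rcpp::export(name = ".cppInterp3")]]
NumericVector cppInterp3(NumericVector arr, IntegerVector dim,
                         NumericVector xi, NumericVector yi,
                         NumericVector zi, bool nearest = false) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = xi.size();
  NumericVector out(n);
  const double* a = arr.begin();
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = clampd(xi[i], 1.0, nx);
    double y = clampd(yi[i], 1.0, ny);
    double z = clampd(zi[i], 1.0, nz);
    if (nearest) {
      // match R's round(): IEC 60559 round-half-even
      int x0 = (int)clampd(std::nearbyint(x), 1, nx);
      int y0 = (int)clampd(std::nearbyint(y), 1, ny);
      int z0 = (int)clampd(std::nearbyint(z), 1, nz);
      out[i] = a[(x0 - 1) + (R_xlen_t)(y0 - 1) * sy + (R_xlen_t)(z0 - 1) * sz];
      continue;
    }
    int x0 = (int)clampd(std::floor(x), 1, nx - 1);
    int y0 = (int)clampd(std::floor(y), 1, ny - 1);
    int z0 = (int)clampd(std::floor(z), 1, nz - 1);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    const double* p = a + (x0 - 1) + (R_xlen_t)(y0 - 1) * sy +
      (R_xlen_t)(z0 - 1) * sz;
    double c00 = p[0] * (1 - fx) + p[1] * fx;
    double c10 = p[sy] * (1 - fx) + p[sy + 1] * fx;
    double c01 = p[sz] * (1 - fx) + p[sz + 1] * fx;
    double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + 1] * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Separable smoothing, processed line by line through a small padded
// buffer (cache-friendly for the strided y/z axes).
// [[Rcpp::export(name = ".cppSmooth3")]]
NumericVector cppSmooth3(NumericVector arr, IntegerVector dim,
                         NumericVector sigmaVox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(arr.begin(), arr.end()), buf;
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int len[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigmaVox[axis];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> w(2 * r + 1);
    double ws = 0;
    for (int k = -r; k <= r; ++k) {
      w[k + r] = std::exp(-0.5 * k * k / (s * s));
      ws += w[k + r];
    }
    for (double& v : w) v /= ws;
    const int na = len[axis];
    const R_xlen_t st = stride[axis];
    const int o1 = (axis == 0) ? 1 : 0, o2 = (axis == 2) ? 1 : 2;
    const int n1 = len[o1], n2 = len[o2];
    const R_xlen_t st1 = stride[o1], st2 = stride[o2];
    buf.assign(na + 2 * r, 0.0);
    for (int j2 = 0; j2 < n2; ++j2)
      for (int j1 = 0; j1 < n1; ++j1) {
        const R_xlen_t base = (R_xlen_t)j1 * st1 + (R_xlen_t)j2 * st2;
        for (int i = 0; i < na; ++i) buf[r + i] = a[base + (R_xlen_t)i * st];
        for (int i = 0; i < r; ++i) { // replicate edges
          buf[i] = buf[r];
          buf[na + r + i] = buf[na + r - 1];
        }
        for (int i = 0; i < na; ++i) {
          double acc = 0;
          for (int k = 0; k < 2 * r + 1; ++k) acc += w[k] * buf[i + k];
          a[base + (R_xlen_t)i * st] = acc;
        }
      }
  }
  NumericVector out(N);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}
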