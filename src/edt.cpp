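// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable per axis with anisotropic voxel spacing. Absent seeds are
// represented by a large finite sentinel so the parabola envelope needs
// no special cases; sentinel-dominated results are mapped back to Inf.

#include <Rcpp.h>
using namespace Rcpp;

static const double BIG = 1e18;

// 1-D squared-distance transform over sample positions x_i = i * h.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double h, int n) {
  std::vector<int> v(n);
  std::vector<double> zz(n + 1);
  int k = 0;
  v[0] = 0;
  zz[0] = -BIG;
  zz[1] = BIG;
  const double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q * h2) -
                (f[v[k]] + (double)v[k] * v[k] * h2)) /
               (2.0 * h * (q - v[k]));
    while (s <= zz[k]) {
      --k;
      s = ((f[q] + (double)q * q * h2) -
           (f[v[k]] + (double)v[k] * v[k] * h2)) /
          (2.0 * h * (q - v[k]));
    }
    ++k;
    v[k] = q;
    zz[k] = s;
    zz[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[k + 1] < (double)q * h) ++k;
    double dq = ((double)q - v[k]) * h;
    d[q] = dq * dq + f[v[k]];
  }
}

// Distance from every voxel to the nearest seed voxel (seed != 0),
// in physical units given the voxel spacing.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector seed, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; ++i) g[i] = seed[i] ? 0.0 : BIG;

  std::vector<double> f, d;
  // x axis
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      size_t base = (size_t)z * nx * ny + (size_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = g[base + x];
      dt1d(f, d, spacing[0], nx);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // y axis
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      size_t base = (size_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = g[base + (size_t)y * nx];
      dt1d(f, d, spacing[1], ny);
      for (int y = 0; y < ny; ++y) g[base + (size_t)y * nx] = d[y];
    }
  // z axis
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      size_t base = (size_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = g[base + (size_t)z * nx * ny];
      dt1d(f, d, spacing[2], nz);
      for (int z = 0; z < nz; ++z) g[base + (size_t)z * nx * ny] = d[z];
    }

  NumericVector out(n);
  for (size_t i = 0; i < n; ++i)
    out[i] = (g[i] >= BIG / 2) ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}
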