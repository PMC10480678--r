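// Parallel-beam projector and OSEM for stacks of axial slices.
//
// Geometry: pixel-driven splatting. For angle theta, a pixel at voxel
// index (ix, iy) projects to the radial coordinate
//   s = (ix - cx) * cos(theta) + (iy - cy) * sin(theta)   [voxel pitch units]
// and its value is distributed linearly over the two adjacent radial bins
// (bin pitch = voxel pitch, bins centred on the grid centre). The adjoint
// uses the same weights, so forward and back projection form an exact
// matched pair. Mass is conserved per angle: the bin sums of one angle
// equal the sum of the slice.

#include <Rcpp.h>
using namespace Rcpp;

// Forward projection of a volume (nx, ny, nz) over the given angles.
// Returns array (nBins, nAngles, nz) of bin sums (unitless splat sums;
// multiply by the voxel pitch to approximate line integrals).
// [[Rcpp::export]]
NumericVector cpp_project(NumericVector vol, int nx, int ny, int nz,
                          NumericVector cosA, NumericVector sinA,
                          int nBins) {
  const int nA = cosA.size();
  NumericVector out(Dimension(nBins, nA, nz));
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double c0 = 0.5 * (nBins - 1);
  const double *v = vol.begin();
  double *o = out.begin();
  for (int z = 0; z < nz; ++z) {
    const double *vz = v + (size_t)z * nx * ny;
    for (int a = 0; a < nA; ++a) {
      const double ca = cosA[a], sa = sinA[a];
      double *oz = o + (size_t)z * nBins * nA + (size_t)a * nBins;
      for (int iy = 0; iy < ny; ++iy) {
        double s = (0 - cx) * ca + (iy - cy) * sa + c0;
        const double *row = vz + (size_t)iy * nx;
        for (int ix = 0; ix < nx; ++ix, s += ca) {
          const double val = row[ix];
          if (val != 0.0) {
            int i0 = (int)std::floor(s);
            double w1 = s - i0;
            if (i0 >= 0 && i0 < nBins) oz[i0] += val * (1.0 - w1);
            if (i0 + 1 >= 0 && i0 + 1 < nBins) oz[i0 + 1] += val * w1;
          }
        }
      }
    }
  }
  return out;
}

// Back projection (exact adjoint of cpp_project).
// sino: (nBins, nAngles, nz); returns (nx, ny, nz).
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector sino, int nx, int ny, int nz,
                              NumericVector cosA, NumericVector sinA,
                              int nBins) {
  const int nA = cosA.size();
  NumericVector out(Dimension(nx, ny, nz));
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double c0 = 0.5 * (nBins - 1);
  const double *sp = sino.begin();
  double *o = out.begin();
  for (int z = 0; z < nz; ++z) {
    double *oz = o + (size_t)z * nx * ny;
    for (int a = 0; a < nA; ++a) {
      const double ca = cosA[a], sa = sinA[a];
      const double *sz = sp + (size_t)z * nBins * nA + (size_t)a * nBins;
      for (int iy = 0; iy < ny; ++iy) {
        double s = (0 - cx) * ca + (iy - cy) * sa + c0;
        double *row = oz + (size_t)iy * nx;
        for (int ix = 0; ix < nx; ++ix, s += ca) {
          int i0 = (int)std::floor(s);
          double w1 = s - i0, acc = 0.0;
          if (i0 >= 0 && i0 < nBins) acc += sz[i0] * (1.0 - w1);
          if (i0 + 1 >= 0 && i0 + 1 < nBins) acc += sz[i0 + 1] * w1;
          row[ix] += acc;
        }
      }
    }
  }
  return out;
}

// Ordered-subsets EM with attenuation factors and a known additive
// background in the forward model.
//   lambda = st * att * P x + bg,   x_{k+1} = x_k * Pt(att y / lambda) / Pt(att)
// counts, att: (nBins, nAngles, nz); bgCell: expected background counts
// per sinogram cell, one value per slice; st = sensitivity * time.
// Subset j uses angles {j, j + nSubsets, ...}; nSubsets must divide nA.
// [[Rcpp::export]]
NumericVector cpp_osem(NumericVector counts, NumericVector att,
                       NumericVector bgCell,
                       NumericVector cosA, NumericVector sinA,
                       int nx, int ny, int nz, int nBins,
                       int nIter, int nSubsets, double st) {
  const int nA = cosA.size();
  if (nA % nSubsets != 0)
    stop("number of subsets (%d) must divide the number of angles (%d)",
         nSubsets, nA);
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double c0 = 0.5 * (nBins - 1);
  const int npix = nx * ny;
  NumericVector x(Dimension(nx, ny, nz));
  std::fill(x.begin(), x.end(), 1.0);
  const double *yC = counts.begin();
  const double *aC = att.begin();
  double *xp = x.begin();

  std::vector<double> proj(nBins), ratio(nBins);
  std::vector<double> num(npix), den(npix);

  for (int z = 0; z < nz; ++z) {
    double *xz = xp + (size_t)z * npix;
    const double bg = bgCell[z];
    const double *yz = yC + (size_t)z * nBins * nA;
    const double *az = aC + (size_t)z * nBins * nA;
    for (int it = 0; it < nIter; ++it) {
      for (int sub = 0; sub < nSubsets; ++sub) {
        std::fill(num.begin(), num.end(), 0.0);
        std::fill(den.begin(), den.end(), 0.0);
        for (int a = sub; a < nA; a += nSubsets) {
          const double ca = cosA[a], sa = sinA[a];
          const double *ya = yz + (size_t)a * nBins;
          const double *aa = az + (size_t)a * nBins;
          // forward project current estimate along this angle
          std::fill(proj.begin(), proj.end(), 0.0);
          for (int iy = 0; iy < ny; ++iy) {
            double s = (0 - cx) * ca + (iy - cy) * sa + c0;
            const double *row = xz + (size_t)iy * nx;
            for (int ix = 0; ix < nx; ++ix, s += ca) {
              const double val = row[ix];
              if (val != 0.0) {
                int i0 = (int)std::floor(s);
                double w1 = s - i0;
                if (i0 >= 0 && i0 < nBins) proj[i0] += val * (1.0 - w1);
                if (i0 + 1 >= 0 && i0 + 1 < nBins) proj[i0 + 1] += val * w1;
              }
            }
          }
          for (int b = 0; b < nBins; ++b) {
            const double lam = st * aa[b] * proj[b] + bg;
            ratio[b] = (lam > 0.0) ? (ya[b] / lam) * aa[b] : 0.0;
          }
          // backproject ratio (numerator) and att (sensitivity)
          for (int iy = 0; iy < ny; ++iy) {
            double s = (0 - cx) * ca + (iy - cy) * sa + c0;
            double *nrow = num.data() + (size_t)iy * nx;
            double *drow = den.data() + (size_t)iy * nx;
            for (int ix = 0; ix < nx; ++ix, s += ca) {
              int i0 = (int)std::floor(s);
              double w1 = s - i0;
              double rn = 0.0, rd = 0.0;
              if (i0 >= 0 && i0 < nBins) {
                rn += ratio[i0] * (1.0 - w1);
                rd += aa[i0] * (1.0 - w1);
              }
              if (i0 + 1 >= 0 && i0 + 1 < nBins) {
                rn += ratio[i0 + 1] * w1;
                rd += aa[i0 + 1] * w1;
              }
              nrow[ix] += rn;
              drow[ix] += rd;
            }
          }
        }
        for (int p = 0; p < npix; ++p) {
          if (den[p] > 0.0) xz[p] *= num[p] / den[p];
        }
        Rcpp::checkUserInterrupt();
      }
    }
  }
  return x;
}

// Faster OSEM: identical model to cpp_osem, but with precomputed splat
// tables, an in-plane support mask (pixels outside it stay 0), and the
// per-subset sensitivity image computed once per slice instead of once
// per subiteration. Produces the same estimate as cpp_osem on supported
// pixels (up to floating-point summation order).
// [[Rcpp::export]]
NumericVector cpp_osem_fast(NumericVector counts, NumericVector att,
                            NumericVector bgCell,
                            NumericVector cosA, NumericVector sinA,
                            int nx, int ny, int nz, int nBins,
                            int nIter, int nSubsets, double st,
                            LogicalVector support) {
  const int nA = cosA.size();
  if (nA % nSubsets != 0)
    stop("number of subsets (%d) must divide the number of angles (%d)",
         nSubsets, nA);
  if (support.size() != nx * ny)
    stop("support mask must be an nx x ny in-plane mask");
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double c0 = 0.5 * (nBins - 1);
  const int npix = nx * ny;

  // supported pixel list and per-(pixel, angle) splat tables
  std::vector<int> pix;
  pix.reserve(npix);
  for (int p = 0; p < npix; ++p)
    if (support[p]) pix.push_back(p);
  const int ns = (int)pix.size();
  if (ns == 0) stop("empty support mask");
  std::vector<int> tbin((size_t)ns * nA);
  std::vector<double> tw((size_t)ns * nA);
  for (int a = 0; a < nA; ++a) {
    const double ca = cosA[a], sa = sinA[a];
    for (int j = 0; j < ns; ++j) {
      const int p = pix[j];
      const int ix = p % nx, iy = p / nx;
      double s = (ix - cx) * ca + (iy - cy) * sa + c0;
      int i0 = (int)std::floor(s);
      double w1 = s - i0;
      if (i0 < 0) { i0 = 0; w1 = 0.0; }
      if (i0 > nBins - 2) { i0 = nBins - 2; w1 = 1.0; }
      tbin[(size_t)a * ns + j] = i0;
      tw[(size_t)a * ns + j] = w1;
    }
  }

  NumericVector x(Dimension(nx, ny, nz)); // zero-initialised
  const double *yC = counts.begin();
  const double *aC = att.begin();
  double *xp = x.begin();

  const int perSub = nA / nSubsets;
  std::vector<double> xs(ns), num(ns);
  std::vector<double> sens((size_t)ns * nSubsets);
  std::vector<double> proj(nBins), ratio(nBins);

  for (int z = 0; z < nz; ++z) {
    double *xz = xp + (size_t)z * npix;
    const double bg = bgCell[z];
    const double *yz = yC + (size_t)z * nBins * nA;
    const double *az = aC + (size_t)z * nBins * nA;

    // per-subset sensitivity for this slice
    std::fill(sens.begin(), sens.end(), 0.0);
    for (int sub = 0; sub < nSubsets; ++sub) {
      double *sn = sens.data() + (size_t)sub * ns;
      for (int a = sub; a < nA; a += nSubsets) {
        const double *aa = az + (size_t)a * nBins;
        const int *tb = tbin.data() + (size_t)a * ns;
        const double *twa = tw.data() + (size_t)a * ns;
        for (int j = 0; j < ns; ++j) {
          const int b = tb[j];
          const double w1 = twa[j];
          sn[j] += aa[b] * (1.0 - w1) + aa[b + 1] * w1;
        }
      }
    }

    std::fill(xs.begin(), xs.end(), 1.0);
    for (int it = 0; it < nIter; ++it) {
      for (int sub = 0; sub < nSubsets; ++sub) {
        std::fill(num.begin(), num.end(), 0.0);
        for (int k = 0; k < perSub; ++k) {
          const int a = sub + k * nSubsets;
          const double *ya = yz + (size_t)a * nBins;
          const double *aa = az + (size_t)a * nBins;
          const int *tb = tbin.data() + (size_t)a * ns;
          const double *twa = tw.data() + (size_t)a * ns;
          std::fill(proj.begin(), proj.end(), 0.0);
          for (int j = 0; j < ns; ++j) {
            const double val = xs[j];
            const int b = tb[j];
            const double w1 = twa[j];
            proj[b] += val * (1.0 - w1);
            proj[b + 1] += val * w1;
          }
          for (int b = 0; b < nBins; ++b) {
            const double lam = st * aa[b] * proj[b] + bg;
            ratio[b] = (lam > 0.0) ? (ya[b] / lam) * aa[b] : 0.0;
          }
          for (int j = 0; j < ns; ++j) {
            const int b = tb[j];
            const double w1 = twa[j];
            num[j] += ratio[b] * (1.0 - w1) + ratio[b + 1] * w1;
          }
        }
        const double *sn = sens.data() + (size_t)sub * ns;
        for (int j = 0; j < ns; ++j)
          if (sn[j] > 0.0) xs[j] *= num[j] / sn[j];
      }
      Rcpp::checkUserInterrupt();
    }
    for (int j = 0; j < ns; ++j) xz[pix[j]] = xs[j];
    Rcpp::checkUserInterrupt();
  }
  return x;
}

// Separable Gaussian filter with replicate padding; kernels are given
// explicitly per axis (odd lengths; pass length-1 kernels to skip).
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, int nx, int ny, int nz,
                          NumericVector kx, NumericVector ky,
                          NumericVector kz) {
  const size_t n = (size_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(n);

  // x axis
  if (kx.size() > 1) {
    const int hw = (kx.size() - 1) / 2;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const double *src = a.data() + (size_t)z * nx * ny + (size_t)y * nx;
        double *dst = b.data() + (size_t)z * nx * ny + (size_t)y * nx;
        for (int i = 0; i < nx; ++i) {
          double acc = 0.0;
          for (int k = -hw; k <= hw; ++k) {
            int j = i + k;
            if (j < 0) j = 0;
            if (j >= nx) j = nx - 1;
            acc += kx[k + hw] * src[j];
          }
          dst[i] = acc;
        }
      }
    a.swap(b);
  }
  // y axis
  if (ky.size() > 1) {
    const int hw = (ky.size() - 1) / 2;
    for (int z = 0; z < nz; ++z) {
      const double *sz = a.data() + (size_t)z * nx * ny;
      double *dz = b.data() + (size_t)z * nx * ny;
      for (int y = 0; y < ny; ++y) {
        double *dst = dz + (size_t)y * nx;
        for (int x2 = 0; x2 < nx; ++x2) dst[x2] = 0.0;
        for (int k = -hw; k <= hw; ++k) {
          int j = y + k;
          if (j < 0) j = 0;
          if (j >= ny) j = ny - 1;
          const double *src = sz + (size_t)j * nx;
          const double w = ky[k + hw];
          for (int x2 = 0; x2 < nx; ++x2) dst[x2] += w * src[x2];
        }
      }
    }
    a.swap(b);
  }
  // z axis
  if (kz.size() > 1) {
    const int hw = (kz.size() - 1) / 2;
    for (int z = 0; z < nz; ++z) {
      double *dz = b.data() + (size_t)z * nx * ny;
      for (size_t i = 0; i < (size_t)nx * ny; ++i) dz[i] = 0.0;
      for (int k = -hw; k <= hw; ++k) {
        int j = z + k;
        if (j < 0) j = 0;
        if (j >= nz) j = nz - 1;
        const double *sz = a.data() + (size_t)j * nx * ny;
        const double w = kz[k + hw];
        for (size_t i = 0; i < (size_t)nx * ny; ++i) dz[i] += w * sz[i];
      }
    }
    a.swap(b);
  }

  NumericVector out(Dimension(nx, ny, nz));
  std::copy(a.begin(), a.end(), out.begin());
  return out;
}
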