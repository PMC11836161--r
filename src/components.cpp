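#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 26-connected component labelling of a 3D foreground mask.
// Thick-slice sagittal acquisitions fragment thin structures under
// 6-connectivity, so the full 26-neighbourhood is used throughout.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int current = 0;
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++current;
    lab[start] = current;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[w] && lab[w] == 0) {
              lab[w] = current;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("n_components") = current;
  return lab;
}

// Exact 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher)
// over sample positions pos[i] = i * step, allowing anisotropic voxels.
static void dt1d(const double *f, double *d, int n, double step) {
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == inf) continue; // no parabola at unreachable sites
    double xq = q * step;
    while (k >= 0) {
      double xv = v[k] * step;
      double s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s > z[k]) { z[k + 1] = s; break; }
      --k;
    }
    if (k < 0) { k = 0; v[0] = q; z[0] = -inf; }
    else { ++k; v[k] = q; }
    z[k + 1] = inf;
  }
  if (k < 0) { // whole line unreachable
    for (int q = 0; q < n; ++q) d[q] = inf;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[j + 1] < xq) ++j;
    double xv = v[j] * step;
    d[q] = (xq - xv) * (xq - xv) + f[v[j]];
  }
}

// Exact Euclidean squared distance transform (mm^2) to the seed set,
// separable across axes with per-axis voxel spacing.
// [[Rcpp::export(name = ".edt_sq_3d")]]
NumericVector edt_sq_3d(LogicalVector seed, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double inf = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = seed[i] ? 0.0 : inf;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  // axis 0
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f.data(), d.data(), nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // axis 1
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * (R_xlen_t)z;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)nx * y];
      dt1d(f.data(), d.data(), ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nx * y] = d[y];
    }
  // axis 2
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int z = 0; z < nz; ++z) f[z] = out[base + stride * z];
      dt1d(f.data(), d.data(), nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + stride * z] = d[z];
    }
  out.attr("dim") = dims;
  return out;
}
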