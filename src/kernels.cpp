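#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Separable correlation of a 3D array (dims nz x ny x nx, column-major) with a
// centred odd-length 1D kernel along one axis (0 = z, 1 = y, 2 = x).
// Edges are replicated so a constant volume stays constant.
// [[Rcpp::export(name = ".conv1d_axis3d")]]
NumericVector conv1d_axis3d(NumericVector arr, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int klen = kernel.size();
  const int hw = klen / 2;
  NumericVector out(arr.size());
  const double* a = arr.begin();
  double* o = out.begin();
  const double* k = kernel.begin();

  if (axis == 0) {
    // contiguous lines along z
    const long nlines = (long)ny * nx;
    std::vector<double> line(nz);
    for (long l = 0; l < nlines; ++l) {
      const long base = l * (long)nz;
      for (int i = 0; i < nz; ++i) line[i] = a[base + i];
      for (int i = 0; i < nz; ++i) {
        double acc = 0.0;
        for (int j = 0; j < klen; ++j) {
          int idx = i + j - hw;
          if (idx < 0) idx = 0;
          else if (idx >= nz) idx = nz - 1;
          acc += line[idx] * k[j];
        }
        o[base + i] = acc;
      }
    }
  } else if (axis == 1) {
    // per x-slab: columns of length nz, accumulate tap-shifted columns
    for (int x = 0; x < nx; ++x) {
      const long slab = (long)nz * ny * x;
      for (int y = 0; y < ny; ++y) {
        double* oc = o + slab + (long)nz * y;
        for (int j = 0; j < klen; ++j) {
          int yy = y + j - hw;
          if (yy < 0) yy = 0;
          else if (yy >= ny) yy = ny - 1;
          const double kj = k[j];
          const double* ac = a + slab + (long)nz * yy;
          if (j == 0) for (int z = 0; z < nz; ++z) oc[z] = kj * ac[z];
          else for (int z = 0; z < nz; ++z) oc[z] += kj * ac[z];
        }
      }
    }
  } else {
    // columns of length nz*ny along x, contiguous AXPY per tap
    const long cl = (long)nz * ny;
    for (int x = 0; x < nx; ++x) {
      double* oc = o + cl * x;
      for (int j = 0; j < klen; ++j) {
        int xx = x + j - hw;
        if (xx < 0) xx = 0;
        else if (xx >= nx) xx = nx - 1;
        const double kj = k[j];
        const double* ac = a + cl * xx;
        if (j == 0) for (long i = 0; i < cl; ++i) oc[i] = kj * ac[i];
        else for (long i = 0; i < cl; ++i) oc[i] += kj * ac[i];
      }
    }
  }
  return out;
}

// 1D parabolic erosion: out[q] = min_p f[p] + curv * (q - p)^2,
// computed exactly via the lower envelope of parabolas.
static void parab_erode_line(const double* f, double* out, int n, double curv,
                             std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + curv * (double)q * q) - (f[p] + curv * (double)p * p)) /
          (2.0 * curv * (q - p));
      if (s <= z[k]) {
        --k;
      } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    out[q] = f[p] + curv * (double)(q - p) * (q - p);
  }
}

// Grayscale erosion of a matrix by a paraboloid structuring function
// z(d) = curv * |d|^2 (separable: rows then columns).
// [[Rcpp::export(name = ".parab_erode2d")]]
NumericMatrix parab_erode2d(NumericMatrix img, double curv) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  int nmax = nr > nc ? nr : nc;
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);
  std::vector<double> buf(nmax), res(nmax);
  // along columns (within each column, over rows)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) buf[r] = img(r, c);
    parab_erode_line(buf.data(), res.data(), nr, curv, v, z);
    for (int r = 0; r < nr; ++r) tmp(r, c) = res[r];
  }
  // along rows (within each row, over columns)
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) buf[c] = tmp(r, c);
    parab_erode_line(buf.data(), res.data(), nc, curv, v, z);
    for (int c = 0; c < nc; ++c) out(r, c) = res[c];
  }
  return out;
}

// Indices (1-based, column-major) of voxels that are strict 26-connected
// local minima of a 3D response and negative. Border voxels are excluded:
// the edge-replicated Laplacian degenerates to a first difference there.
// [[Rcpp::export(name = ".local_minima3d")]]
IntegerVector local_minima3d(NumericVector arr, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double* a = arr.begin();
  std::vector<int> hits;
  const int x0 = nx > 2 ? 1 : 0, x1 = nx > 2 ? nx - 1 : nx;
  const int y0 = ny > 2 ? 1 : 0, y1 = ny > 2 ? ny - 1 : ny;
  const int z0 = nz > 2 ? 1 : 0, z1 = nz > 2 ? nz - 1 : nz;
  for (int x = x0; x < x1; ++x) {
    for (int y = y0; y < y1; ++y) {
      for (int z = z0; z < z1; ++z) {
        long idx = z + (long)nz * (y + (long)ny * x);
        double v = a[idx];
        if (!(v < 0)) continue;
        bool ok = true;
        for (int dx = -1; dx <= 1 && ok; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          for (int dy = -1; dy <= 1 && ok; ++dy) {
            int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            for (int dz = -1; dz <= 1; ++dz) {
              int zz = z + dz;
              if (zz < 0 || zz >= nz) continue;
              if (dx == 0 && dy == 0 && dz == 0) continue;
              if (!(v < a[zz + (long)nz * (yy + (long)ny * xx)])) {
                ok = false;
                break;
              }
            }
          }
        }
        if (ok) hits.push_back((int)(idx + 1));
      }
    }
  }
  return wrap(hits);
}
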