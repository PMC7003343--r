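#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
using namespace Rcpp;

// Gray levels are stored as a flat integer vector in R array order
// (x fastest), with NA_INTEGER outside the mask.

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Co-occurrence counts for a set of 3D offsets at voxel distance 1.
// Returns an nLevels x nLevels x nDir array of symmetrized raw counts.
// [[Rcpp::export]]
NumericVector cpp_glcm_counts(IntegerVector levels, IntegerVector dims,
                              int nLevels, IntegerMatrix offsets) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nd = offsets.nrow();
  NumericVector out(nLevels * nLevels * nd);
  for (int d = 0; d < nd; ++d) {
    int ox = offsets(d, 0), oy = offsets(d, 1), oz = offsets(d, 2);
    double *cnt = &out[(size_t)d * nLevels * nLevels];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = levels[idx3(x, y, z, nx, ny)];
          if (a == NA_INTEGER) continue;
          int x2 = x + ox, y2 = y + oy, z2 = z + oz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          int b = levels[idx3(x2, y2, z2, nx, ny)];
          if (b == NA_INTEGER) continue;
          cnt[(a - 1) + nLevels * (b - 1)] += 1.0;
          cnt[(b - 1) + nLevels * (a - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(nLevels, nLevels, nd);
  return out;
}

// Run-length matrices: maximal colinear same-level in-mask segments.
// Returns nLevels x maxLen x nDir counts.
// [[Rcpp::export]]
NumericVector cpp_rlm_counts(IntegerVector levels, IntegerVector dims,
                             int nLevels, IntegerMatrix offsets, int maxLen) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nd = offsets.nrow();
  NumericVector out(nLevels * maxLen * nd);
  for (int d = 0; d < nd; ++d) {
    int ox = offsets(d, 0), oy = offsets(d, 1), oz = offsets(d, 2);
    double *cnt = &out[(size_t)d * nLevels * maxLen];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = levels[idx3(x, y, z, nx, ny)];
          if (a == NA_INTEGER) continue;
          // run start: predecessor along -offset absent or different
          int xp = x - ox, yp = y - oy, zp = z - oz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz) {
            int p = levels[idx3(xp, yp, zp, nx, ny)];
            if (p != NA_INTEGER && p == a) continue;
          }
          int len = 1;
          int xc = x + ox, yc = y + oy, zc = z + oz;
          while (xc >= 0 && xc < nx && yc >= 0 && yc < ny && zc >= 0 && zc < nz) {
            int b = levels[idx3(xc, yc, zc, nx, ny)];
            if (b == NA_INTEGER || b != a) break;
            ++len; xc += ox; yc += oy; zc += oz;
          }
          if (len > maxLen) len = maxLen;
          cnt[(a - 1) + nLevels * (len - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(nLevels, maxLen, nd);
  return out;
}

// 26-connected same-level zones. Returns a two-column matrix (level, size).
// [[Rcpp::export]]
IntegerMatrix cpp_zone_sizes(IntegerVector levels, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zlev, zsize;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (seen[i] || levels[i] == NA_INTEGER) continue;
    int lev = levels[i];
    int size = 0;
    stack.clear();
    stack.push_back(i);
    seen[i] = 1;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      ++size;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
              continue;
            int w = idx3(x2, y2, z2, nx, ny);
            if (!seen[w] && levels[w] != NA_INTEGER && levels[w] == lev) {
              seen[w] = 1;
              stack.push_back(w);
            }
          }
    }
    zlev.push_back(lev);
    zsize.push_back(size);
  }
  IntegerMatrix out(zlev.size(), 2);
  for (size_t k = 0; k < zlev.size(); ++k) {
    out(k, 0) = zlev[k];
    out(k, 1) = zsize[k];
  }
  return out;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) with grid step w.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double w, int n) {
  std::vector<int> v(n);
  std::vector<double> zz(n + 1);
  int k = 0;
  v[0] = 0;
  zz[0] = -INFINITY;
  zz[1] = INFINITY;
  double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= zz[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zz[k] = s;
    zz[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance transform: for every voxel, distance (mm) to the nearest
// site voxel (site = TRUE), with anisotropic spacing.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector site, IntegerVector dims,
                      NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<double> g(n);
  const double INF = 1e30;
  for (int i = 0; i < n; ++i) g[i] = site[i] ? 0.0 : INF;
  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());
  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = g[idx3(x, y, z, nx, ny)];
      dt1d(f, d, spacing[0], nx);
      for (int x = 0; x < nx; ++x) g[idx3(x, y, z, nx, ny)] = d[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = g[idx3(x, y, z, nx, ny)];
      dt1d(f, d, spacing[1], ny);
      for (int y = 0; y < ny; ++y) g[idx3(x, y, z, nx, ny)] = d[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = g[idx3(x, y, z, nx, ny)];
      dt1d(f, d, spacing[2], nz);
      for (int z = 0; z < nz; ++z) g[idx3(x, y, z, nx, ny)] = d[z];
    }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}

// Maximum pairwise Euclidean distance between points (rows, in mm).
// [[Rcpp::export]]
double cpp_max_pair_dist(NumericMatrix pts) {
  int n = pts.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
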