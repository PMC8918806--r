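#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Arrays are column-major with dim = c(nz, ny, nx); linear index
// idx = iz + nz * (iy + ny * ix), all 0-based.

static inline int at(int iz, int iy, int ix, int nz, int ny) {
  return iz + nz * (iy + ny * ix);
}

// reflect index into [0, n-1] (mirror boundary, no repeated edge sample
// for n > 1; degenerate n == 1 clamps)
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector conv_sep3d_cpp(NumericVector arr, NumericVector kz,
                             NumericVector ky, NumericVector kx) {
  IntegerVector d = arr.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  const R_xlen_t n = arr.size();
  std::vector<double> a(arr.begin(), arr.end()), b(n);

  // convolve along z
  {
    const int kl = kz.size(), hw = kl / 2;
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny; ++iy)
        for (int iz = 0; iz < nz; ++iz) {
          double s = 0.0;
          for (int k = 0; k < kl; ++k)
            s += kz[k] * a[at(reflect(iz + k - hw, nz), iy, ix, nz, ny)];
          b[at(iz, iy, ix, nz, ny)] = s;
        }
    a.swap(b);
  }
  // along y
  {
    const int kl = ky.size(), hw = kl / 2;
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny; ++iy)
        for (int iz = 0; iz < nz; ++iz) {
          double s = 0.0;
          for (int k = 0; k < kl; ++k)
            s += ky[k] * a[at(iz, reflect(iy + k - hw, ny), ix, nz, ny)];
          b[at(iz, iy, ix, nz, ny)] = s;
        }
    a.swap(b);
  }
  // along x
  {
    const int kl = kx.size(), hw = kl / 2;
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny; ++iy)
        for (int iz = 0; iz < nz; ++iz) {
          double s = 0.0;
          for (int k = 0; k < kl; ++k)
            s += kx[k] * a[at(iz, iy, reflect(ix + k - hw, nx), nz, ny)];
          b[at(iz, iy, ix, nz, ny)] = s;
        }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = d;
  return out;
}

// Eigenvalues of a symmetric 3x3 matrix, analytic (Smith's method),
// returned sorted descending l1 >= l2 >= l3.
static inline void eig3_sym(double a11, double a22, double a33, double a12,
                            double a13, double a23, double ev[3]) {
  const double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0.0) {
    ev[0] = a11; ev[1] = a22; ev[2] = a33;
  } else {
    const double q = (a11 + a22 + a33) / 3.0;
    const double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                      (a33 - q) * (a33 - q) + 2.0 * p1;
    const double p = std::sqrt(p2 / 6.0);
    // B = (A - q I) / p ; r = det(B) / 2
    const double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
    const double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
    double r = (b11 * (b22 * b33 - b23 * b23) - b12 * (b12 * b33 - b23 * b13) +
                b13 * (b12 * b23 - b22 * b13)) / 2.0;
    r = std::max(-1.0, std::min(1.0, r));
    const double phi = std::acos(r) / 3.0;
    ev[0] = q + 2.0 * p * std::cos(phi);
    ev[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    ev[1] = 3.0 * q - ev[0] - ev[2];
  }
  if (ev[0] < ev[1]) std::swap(ev[0], ev[1]);
  if (ev[1] < ev[2]) std::swap(ev[1], ev[2]);
  if (ev[0] < ev[1]) std::swap(ev[0], ev[1]);
}

// Sato-style tubeness from the six Hessian component volumes:
// sqrt(l2 * l3) where l1 >= l2 >= l3, response only when l2 < 0 and l3 < 0
// (bright curvilinear structure), else 0.
// [[Rcpp::export]]
NumericVector tubeness_from_hessian_cpp(NumericVector hzz, NumericVector hyy,
                                        NumericVector hxx, NumericVector hzy,
                                        NumericVector hzx, NumericVector hyx) {
  const R_xlen_t n = hzz.size();
  NumericVector out(n);
  double ev[3];
  for (R_xlen_t i = 0; i < n; ++i) {
    eig3_sym(hzz[i], hyy[i], hxx[i], hzy[i], hzx[i], hyx[i], ev);
    out[i] = (ev[1] < 0.0 && ev[2] < 0.0) ? std::sqrt(ev[1] * ev[2]) : 0.0;
  }
  out.attr("dim") = hzz.attr("dim");
  return out;
}

// ---- exact Euclidean distance transform -------------------------------
// Felzenszwalb & Huttenlocher lower-envelope transform of one scanline of
// squared distances, with anisotropic step w (squared parabola width).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double w2) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// Squared distance from each foreground voxel to the nearest background
// voxel; 0 on background. Weights are physical step sizes per axis.
// [[Rcpp::export]]
NumericVector edt3d_cpp(IntegerVector mask, double wz, double wy, double wx) {
  IntegerVector d = mask.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  const R_xlen_t n = mask.size();
  // large finite "infinity": avoids NaN arithmetic inside the envelope scan
  const double BIG = (wz * nz) * (wz * nz) + (wy * ny) * (wy * ny) +
                     (wx * nx) * (wx * nx) + 1.0;
  std::vector<double> a(n);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = mask[i] ? BIG : 0.0;

  // pass along z
  {
    std::vector<double> f(nz), out(nz);
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny; ++iy) {
        for (int iz = 0; iz < nz; ++iz)
          f[iz] = a[at(iz, iy, ix, nz, ny)];
        dt1d(f, out, nz, wz * wz);
        for (int iz = 0; iz < nz; ++iz) a[at(iz, iy, ix, nz, ny)] = out[iz];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), out(ny);
    for (int ix = 0; ix < nx; ++ix)
      for (int iz = 0; iz < nz; ++iz) {
        for (int iy = 0; iy < ny; ++iy)
          f[iy] = a[at(iz, iy, ix, nz, ny)];
        dt1d(f, out, ny, wy * wy);
        for (int iy = 0; iy < ny; ++iy) a[at(iz, iy, ix, nz, ny)] = out[iy];
      }
  }
  // pass along x
  {
    std::vector<double> f(nx), out(nx);
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        for (int ix = 0; ix < nx; ++ix)
          f[ix] = a[at(iz, iy, ix, nz, ny)];
        dt1d(f, out, nx, wx * wx);
        for (int ix = 0; ix < nx; ++ix) a[at(iz, iy, ix, nz, ny)] = out[ix];
      }
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = d;
  return out;
}

// ---- topology helpers --------------------------------------------------

// 26-neighbourhood offsets
static const int OFF26[26][3] = {
  {-1,-1,-1},{-1,-1,0},{-1,-1,1},{-1,0,-1},{-1,0,0},{-1,0,1},{-1,1,-1},
  {-1,1,0},{-1,1,1},{0,-1,-1},{0,-1,0},{0,-1,1},{0,0,-1},{0,0,1},{0,1,-1},
  {0,1,0},{0,1,1},{1,-1,-1},{1,-1,0},{1,-1,1},{1,0,-1},{1,0,0},{1,0,1},
  {1,1,-1},{1,1,0},{1,1,1}};
static const int OFF6[6][3] = {
  {-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};

// local 3x3x3 cube index: (dz+1) + 3*(dy+1) + 9*(dx+1), centre = 13
static inline int cube_idx(int dz, int dy, int dx) {
  return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
}

// simple-point test (Malandain & Bertrand characterisation):
// exactly one 26-component of foreground in N26, and exactly one
// 6-component of background in N18 that is 6-adjacent to the centre.
static bool is_simple(const std::vector<unsigned char>& fg, int iz, int iy,
                      int ix, int nz, int ny, int nx) {
  unsigned char nb[27];  // local foreground map, centre excluded from tests
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        const int z = iz + dz, y = iy + dy, x = ix + dx;
        const bool in = z >= 0 && z < nz && y >= 0 && y < ny && x >= 0 && x < nx;
        nb[cube_idx(dz, dy, dx)] = (in && fg[at(z, y, x, nz, ny)]) ? 1 : 0;
      }

  // foreground 26-components in N26 (exclude centre 13)
  {
    int comp = 0;
    bool seen[27] = {false};
    for (int s = 0; s < 27; ++s) {
      if (s == 13 || !nb[s] || seen[s]) continue;
      ++comp;
      if (comp > 1) return false;
      // BFS over 26-adjacency within the cube
      std::vector<int> stack(1, s);
      seen[s] = true;
      while (!stack.empty()) {
        const int c = stack.back();
        stack.pop_back();
        const int cz = c % 3 - 1, cy = (c / 3) % 3 - 1, cx = c / 9 - 1;
        for (int k = 0; k < 26; ++k) {
          const int z = cz + OFF26[k][0], y = cy + OFF26[k][1],
                    x = cx + OFF26[k][2];
          if (z < -1 || z > 1 || y < -1 || y > 1 || x < -1 || x > 1) continue;
          const int t = cube_idx(z, y, x);
          if (t == 13 || seen[t] || !nb[t]) continue;
          seen[t] = true;
          stack.push_back(t);
        }
      }
    }
    if (comp != 1) return false;
  }

  // background 6-components in N18 touching the centre face-neighbours
  {
    // N18 = positions with |dz|+|dy|+|dx| <= 2 excluding centre
    bool seen[27] = {false};
    int comp = 0;
    for (int f = 0; f < 6; ++f) {
      const int s = cube_idx(OFF6[f][0], OFF6[f][1], OFF6[f][2]);
      if (nb[s] || seen[s]) continue;
      ++comp;
      if (comp > 1) return false;
      std::vector<int> stack(1, s);
      seen[s] = true;
      while (!stack.empty()) {
        const int c = stack.back();
        stack.pop_back();
        const int cz = c % 3 - 1, cy = (c / 3) % 3 - 1, cx = c / 9 - 1;
        for (int k = 0; k < 6; ++k) {
          const int z = cz + OFF6[k][0], y = cy + OFF6[k][1],
                    x = cx + OFF6[k][2];
          if (z < -1 || z > 1 || y < -1 || y > 1 || x < -1 || x > 1) continue;
          if (std::abs(z) + std::abs(y) + std::abs(x) > 2) continue;  // N18
          const int t = cube_idx(z, y, x);
          if (t == 13 || seen[t] || nb[t]) continue;
          seen[t] = true;
          stack.push_back(t);
        }
      }
    }
    if (comp != 1) return false;
  }
  return true;
}

static inline int count_nbrs26(const std::vector<unsigned char>& fg, int iz,
                               int iy, int ix, int nz, int ny, int nx) {
  int c = 0;
  for (int k = 0; k < 26; ++k) {
    const int z = iz + OFF26[k][0], y = iy + OFF26[k][1], x = ix + OFF26[k][2];
    if (z >= 0 && z < nz && y >= 0 && y < ny && x >= 0 && x < nx &&
        fg[at(z, y, x, nz, ny)])
      ++c;
  }
  return c;
}

// Layer-by-layer 3D thinning to a curve skeleton, in the style of the
// classical 6-subiteration schemes: each full iteration peels, for each
// of the 6 face directions in turn, the border voxels open to that
// direction that are simple points and not curve endpoints (<= 1
// foreground neighbour). Candidates are collected in parallel per
// subiteration and deleted sequentially with the simple-point test
// re-checked, so foreground 26-connectivity is preserved exactly.
// Iterates until stable.
// [[Rcpp::export]]
IntegerVector thin3d_cpp(IntegerVector mask) {
  IntegerVector d = mask.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  const R_xlen_t n = mask.size();
  std::vector<unsigned char> fg(n);
  for (R_xlen_t i = 0; i < n; ++i) fg[i] = mask[i] ? 1 : 0;

  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      const int dz = OFF6[dir][0], dy = OFF6[dir][1], dx = OFF6[dir][2];
      cand.clear();
      for (int ix = 0; ix < nx; ++ix)
        for (int iy = 0; iy < ny; ++iy)
          for (int iz = 0; iz < nz; ++iz) {
            const R_xlen_t i = at(iz, iy, ix, nz, ny);
            if (!fg[i]) continue;
            // border in this direction? (outside counts as background)
            const int z = iz + dz, y = iy + dy, x = ix + dx;
            const bool nb_fg = z >= 0 && z < nz && y >= 0 && y < ny &&
                               x >= 0 && x < nx && fg[at(z, y, x, nz, ny)];
            if (nb_fg) continue;
            const int nn = count_nbrs26(fg, iz, iy, ix, nz, ny, nx);
            if (nn <= 1) continue;  // endpoint or isolated: keep
            if (!is_simple(fg, iz, iy, ix, nz, ny, nx)) continue;
            cand.push_back(i);
          }
      for (size_t c = 0; c < cand.size(); ++c) {
        const R_xlen_t i = cand[c];
        const int ix = (int)(i / ((R_xlen_t)nz * ny));
        const int iy = (int)((i / nz) % ny);
        const int iz = (int)(i % nz);
        const int nn = count_nbrs26(fg, iz, iy, ix, nz, ny, nx);
        if (nn <= 1) continue;
        if (!is_simple(fg, iz, iy, ix, nz, ny, nx)) continue;
        fg[i] = 0;
        changed = true;
      }
    }
  }

  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fg[i];
  out.attr("dim") = d;
  return out;
}

// Connected-component labelling, connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector label3d_cpp(IntegerVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n);
  lab.attr("dim") = d;
  const int noff = (connectivity == 6) ? 6 : 26;
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++cur;
    stack.assign(1, i);
    while (!stack.empty()) {
      const R_xlen_t c = stack.back();
      stack.pop_back();
      const int ix = (int)(c / ((R_xlen_t)nz * ny));
      const int iy = (int)((c / nz) % ny);
      const int iz = (int)(c % nz);
      for (int k = 0; k < noff; ++k) {
        const int z = iz + (noff == 6 ? OFF6[k][0] : OFF26[k][0]);
        const int y = iy + (noff == 6 ? OFF6[k][1] : OFF26[k][1]);
        const int x = ix + (noff == 6 ? OFF6[k][2] : OFF26[k][2]);
        if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
        const R_xlen_t j = at(z, y, x, nz, ny);
        if (mask[j] && !lab[j]) {
          lab[j] = cur;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// Resample a volume through an affine index map: continuous input index
// (zi, yi, xi) = A %*% (zo, yo, xo) + b for each output voxel (0-based).
// A is 3x3 column-major, rows/cols ordered (z, y, x).
// linear = trilinear interpolation, else nearest neighbour; outside -> fill.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector arr, IntegerVector out_dim,
                                  NumericVector A, NumericVector b,
                                  bool linear, double fill) {
  IntegerVector d = arr.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  const int mz = out_dim[0], my = out_dim[1], mx = out_dim[2];
  NumericVector out((R_xlen_t)mz * my * mx);
  const double a11 = A[0], a21 = A[1], a31 = A[2], a12 = A[3], a22 = A[4],
               a32 = A[5], a13 = A[6], a23 = A[7], a33 = A[8];
  for (int ox = 0; ox < mx; ++ox)
    for (int oy = 0; oy < my; ++oy)
      for (int oz = 0; oz < mz; ++oz) {
        const double zi = a11 * oz + a12 * oy + a13 * ox + b[0];
        const double yi = a21 * oz + a22 * oy + a23 * ox + b[1];
        const double xi = a31 * oz + a32 * oy + a33 * ox + b[2];
        double v;
        if (linear) {
          const int z0 = (int)std::floor(zi), y0 = (int)std::floor(yi),
                    x0 = (int)std::floor(xi);
          if (z0 < -1 || z0 > nz - 1 || y0 < -1 || y0 > ny - 1 || x0 < -1 ||
              x0 > nx - 1) {
            v = fill;
          } else {
            const double fz = zi - z0, fy = yi - y0, fx = xi - x0;
            double acc = 0.0;
            for (int dz = 0; dz <= 1; ++dz)
              for (int dy = 0; dy <= 1; ++dy)
                for (int dx = 0; dx <= 1; ++dx) {
                  const int z = z0 + dz, y = y0 + dy, x = x0 + dx;
                  const double w = (dz ? fz : 1 - fz) * (dy ? fy : 1 - fy) *
                                   (dx ? fx : 1 - fx);
                  double s = fill;
                  if (z >= 0 && z < nz && y >= 0 && y < ny && x >= 0 && x < nx)
                    s = arr[at(z, y, x, nz, ny)];
                  acc += w * s;
                }
            v = acc;
          }
        } else {
          const int z = (int)std::lround(zi), y = (int)std::lround(yi),
                    x = (int)std::lround(xi);
          v = (z >= 0 && z < nz && y >= 0 && y < ny && x >= 0 && x < nx)
                  ? arr[at(z, y, x, nz, ny)]
                  : fill;
        }
        out[at(oz, oy, ox, mz, my)] = v;
      }
  out.attr("dim") = out_dim;
  return out;
}

// Count of foreground 26-neighbours for every voxel of a mask (used for
// skeleton junction/endpoint classification).
// [[Rcpp::export]]
IntegerVector neighbor_count26_cpp(IntegerVector mask) {
  IntegerVector d = mask.attr("dim");
  const int nz = d[0], ny = d[1], nx = d[2];
  IntegerVector out(mask.size());
  out.attr("dim") = d;
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        int c = 0;
        for (int k = 0; k < 26; ++k) {
          const int z = iz + OFF26[k][0], y = iy + OFF26[k][1],
                    x = ix + OFF26[k][2];
          if (z >= 0 && z < nz && y >= 0 && y < ny && x >= 0 && x < nx &&
              mask[at(z, y, x, nz, ny)])
            ++c;
        }
        out[at(iz, iy, ix, nz, ny)] = c;
      }
  return out;
}
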