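// Low-level voxel operations on 3D volumes stored as R arrays dim = (nx, ny, nz).
// All coordinates are 0-based voxel-center coordinates (x fastest-varying).
#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline double getv(const double* v, int nx, int ny, int nz,
                          int i, int j, int k) {
  if (i < 0) i = 0; if (i >= nx) i = nx - 1;
  if (j < 0) j = 0; if (j >= ny) j = ny - 1;
  if (k < 0) k = 0; if (k >= nz) k = nz - 1;
  return v[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
}

// Trilinear sample of vol at pts (n x 3, 0-based). Outside: clamped to edge
// when clamp = true, otherwise filled with `fill`.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts, bool clamp, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = vol.begin();
  int n = pts.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!clamp && (x < 0 || y < 0 || z < 0 ||
                   x > nx - 1 || y > ny - 1 || z > nz - 1)) {
      out[p] = fill;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c = 0.0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          if (w != 0.0) c += w * getv(v, nx, ny, nz, i0 + di, j0 + dj, k0 + dk);
        }
    out[p] = c;
  }
  return out;
}

// Trilinear sample plus analytic spatial gradient of the interpolant.
// Returns n x 4 matrix: value, d/dx, d/dy, d/dz.
// [[Rcpp::export]]
NumericMatrix cpp_trilinear_grad(NumericVector vol, IntegerVector dim,
                                 NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = vol.begin();
  int n = pts.nrow();
  NumericMatrix out(n, 4);
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    // keep the cell inside so the gradient stays defined at the domain edge
    if (i0 < 0) i0 = 0; if (i0 > nx - 2) i0 = nx - 2;
    if (j0 < 0) j0 = 0; if (j0 > ny - 2) j0 = ny - 2;
    if (k0 < 0) k0 = 0; if (k0 > nz - 2) k0 = nz - 2;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double val = 0, gx = 0, gy = 0, gz = 0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          double c = getv(v, nx, ny, nz, i0 + di, j0 + dj, k0 + dk);
          double wx = di ? fx : 1 - fx, wy = dj ? fy : 1 - fy, wz = dk ? fz : 1 - fz;
          val += c * wx * wy * wz;
          gx += c * (di ? 1.0 : -1.0) * wy * wz;
          gy += c * wx * (dj ? 1.0 : -1.0) * wz;
          gz += c * wx * wy * (dk ? 1.0 : -1.0);
        }
    out(p, 0) = val; out(p, 1) = gx; out(p, 2) = gy; out(p, 3) = gz;
  }
  return out;
}

// Separable Gaussian blur. Replicate padding by default; zero padding when
// zeropad (so blurring commutes with content-truncating shifts on a zero
// background, as required by the registration pre-blur).
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector vol, IntegerVector dim, double sigma,
                             bool zeropad = false) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  if (sigma <= 0) return clone(vol);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + r];
  }
  for (auto& k : ker) k /= s;
  size_t ntot = (size_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(ntot);
  int dims[3] = {nx, ny, nz};
  size_t strides[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    int nAx = dims[ax];
    size_t st = strides[ax];
    // iterate over all lines along axis ax
    int n1 = dims[(ax + 1) % 3], n2 = dims[(ax + 2) % 3];
    size_t st1 = strides[(ax + 1) % 3], st2 = strides[(ax + 2) % 3];
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1) {
        size_t base = st1 * i1 + st2 * i2;
        for (int i = 0; i < nAx; ++i) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int ii = i + t;
            if (ii < 0 || ii >= nAx) {
              if (zeropad) continue;
              ii = ii < 0 ? 0 : nAx - 1;
            }
            acc += ker[t + r] * a[base + st * ii];
          }
          b[base + st * i] = acc;
        }
      }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// 2x box-filter downsample (each output voxel is the mean of its 2x2x2 block).
// [[Rcpp::export]]
NumericVector cpp_downsample2(NumericVector vol, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int mx = (nx + 1) / 2, my = (ny + 1) / 2, mz = (nz + 1) / 2;
  const double* v = vol.begin();
  NumericVector out((size_t)mx * my * mz);
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        double acc = 0; int cnt = 0;
        for (int dk = 0; dk <= 1; ++dk)
          for (int dj = 0; dj <= 1; ++dj)
            for (int di = 0; di <= 1; ++di) {
              int ii = 2 * i + di, jj = 2 * j + dj, kk = 2 * k + dk;
              if (ii < nx && jj < ny && kk < nz) {
                acc += v[(size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * kk)];
                ++cnt;
              }
            }
        out[(size_t)i + (size_t)mx * ((size_t)j + (size_t)my * k)] = acc / cnt;
      }
  out.attr("dim") = IntegerVector::create(mx, my, mz);
  return out;
}

// Voxels whose 26-neighborhood (or 6- when conn = 6) contains both 0 and 1.
// Returns m x 3 matrix of 0-based coordinates of foreground-and-background
// mixed-neighborhood voxels restricted to foreground ones when fg_only.
// [[Rcpp::export]]
IntegerMatrix cpp_boundary_voxels(IntegerVector vol, IntegerVector dim,
                                  int conn, bool fg_only) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int* v = vol.begin();
  std::vector<int> xs, ys, zs;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = v[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
        if (fg_only && c == 0) continue;
        // the neighborhood includes the voxel itself
        bool seen0 = (c == 0), seen1 = (c != 0);
        for (int dk = -1; dk <= 1 && !(seen0 && seen1); ++dk)
          for (int dj = -1; dj <= 1 && !(seen0 && seen1); ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              if (conn == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) != 1)
                continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              int nb = v[(size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * kk)];
              if (nb) seen1 = true; else seen0 = true;
              if (seen0 && seen1) break;
            }
        if (seen0 && seen1) { xs.push_back(i); ys.push_back(j); zs.push_back(k); }
      }
  IntegerMatrix out(xs.size(), 3);
  for (size_t t = 0; t < xs.size(); ++t) {
    out(t, 0) = xs[t]; out(t, 1) = ys[t]; out(t, 2) = zs[t];
  }
  return out;
}

// Connected-component labeling of the nonzero set of a 2D slice.
// conn in {4, 8}. Returns integer matrix of labels, 0 = background of the set.
// [[Rcpp::export]]
IntegerMatrix cpp_label2d(IntegerMatrix img, int conn) {
  int nx = img.nrow(), ny = img.ncol();
  IntegerMatrix lab(nx, ny);
  int next = 0;
  std::queue<std::pair<int,int> > q;
  const int dx8[8] = {1,-1,0,0,1,1,-1,-1}, dy8[8] = {0,0,1,-1,1,-1,1,-1};
  int ndirs = (conn == 8) ? 8 : 4;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (!img(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        int ci = q.front().first, cj = q.front().second; q.pop();
        for (int d = 0; d < ndirs; ++d) {
          int ii = ci + dx8[d], jj = cj + dy8[d];
          if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
          if (img(ii, jj) && !lab(ii, jj)) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  return lab;
}

// Connected-component labeling of the nonzero set of a 3D volume, conn in {6, 26}.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector vol, IntegerVector dim, int conn) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int* v = vol.begin();
  size_t ntot = (size_t)nx * ny * nz;
  IntegerVector lab(ntot);
  int* L = lab.begin();
  int next = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < ntot; ++s) {
    if (!v[s] || L[s]) continue;
    L[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      size_t c = q.front(); q.pop();
      int ci = c % nx, cj = (c / nx) % ny, ck = c / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int man = std::abs(di) + std::abs(dj) + std::abs(dk);
            if (conn == 6 && man != 1) continue;
            int ii = ci + di, jj = cj + dj, kk = ck + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            size_t t = (size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * kk);
            if (v[t] && !L[t]) { L[t] = next; q.push(t); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Multi-source BFS chamfer-style distance (4-connected, unit steps) from the
// nonzero seed set over the full 2D slice. Returns distances (double).
// [[Rcpp::export]]
NumericMatrix cpp_bfs_dist2d(IntegerMatrix seed) {
  int nx = seed.nrow(), ny = seed.ncol();
  NumericMatrix dist(nx, ny);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  std::queue<std::pair<int,int> > q;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (seed(i, j)) { dist(i, j) = 0; q.push(std::make_pair(i, j)); }
  const int dx[4] = {1,-1,0,0}, dy[4] = {0,0,1,-1};
  while (!q.empty()) {
    int ci = q.front().first, cj = q.front().second; q.pop();
    for (int d = 0; d < 4; ++d) {
      int ii = ci + dx[d], jj = cj + dy[d];
      if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
      if (dist(ii, jj) > dist(ci, cj) + 1) {
        dist(ii, jj) = dist(ci, cj) + 1;
        q.push(std::make_pair(ii, jj));
      }
    }
  }
  return dist;
}
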