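#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Volumes are numeric 3-D arrays in R's column-major order, dims (nx, ny, nz).
// Voxel coordinates are 0-based throughout the C++ layer.

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

static inline double sample_trilinear(const double *v, int nx, int ny, int nz,
                                      double x, double y, double z) {
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zz = z0 + dz;
    if (zz < 0 || zz >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy <= 1; ++dy) {
      int yy = y0 + dy;
      if (yy < 0 || yy >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx <= 1; ++dx) {
        int xx = x0 + dx;
        if (xx < 0 || xx >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        acc += wx * wy * wz * v[idx3(xx, yy, zz, nx, ny)];
      }
    }
  }
  return acc;
}

static inline double sample_nn(const double *v, int nx, int ny, int nz,
                               double x, double y, double z) {
  int xx = (int)std::lround(x), yy = (int)std::lround(y), zz = (int)std::lround(z);
  if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) return 0.0;
  return v[idx3(xx, yy, zz, nx, ny)];
}

// Resample `vol` onto a grid of dims `dim_out`; output voxel p maps to input
// coordinate A %*% p + b (A: 3x3, b: length 3), all 0-based voxel units.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector vol, IntegerVector dim_out,
                                  NumericMatrix A, NumericVector b,
                                  bool linear) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int ox = dim_out[0], oy = dim_out[1], oz = dim_out[2];
  NumericVector out(ox * (R_xlen_t)oy * oz);
  const double *v = REAL(vol);
  double *o = REAL(out);
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x) {
        double sx = A(0,0)*x + A(0,1)*y + A(0,2)*z + b[0];
        double sy = A(1,0)*x + A(1,1)*y + A(1,2)*z + b[1];
        double sz = A(2,0)*x + A(2,1)*y + A(2,2)*z + b[2];
        o[idx3(x, y, z, ox, oy)] = linear
          ? sample_trilinear(v, nx, ny, nz, sx, sy, sz)
          : sample_nn(v, nx, ny, nz, sx, sy, sz);
      }
  out.attr("dim") = dim_out;
  return out;
}

// Sample `vol` at arbitrary coordinate arrays (same length), 0-based.
// [[Rcpp::export]]
NumericVector cpp_sample_at(NumericVector vol, NumericVector X,
                            NumericVector Y, NumericVector Z, bool linear) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t n = X.size();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = linear ? sample_trilinear(v, nx, ny, nz, X[i], Y[i], Z[i])
                    : sample_nn(v, nx, ny, nz, X[i], Y[i], Z[i]);
  return out;
}

// Number of foreground voxels among the 26 neighbours of every voxel.
// [[Rcpp::export]]
IntegerVector cpp_neighbor_count26(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  IntegerVector out(mask.size());
  const int *m = LOGICAL(mask);
  int *o = INTEGER(out);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x+dx, yy = y+dy, zz = z+dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                continue;
              if (m[idx3(xx, yy, zz, nx, ny)]) ++cnt;
            }
        o[idx3(x, y, z, nx, ny)] = cnt;
      }
  out.attr("dim") = d;
  return out;
}

// Connected-component labelling, 26- or 6-connectivity, BFS.
// [[Rcpp::export]]
IntegerVector cpp_cc_label(LogicalVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t n = mask.size();
  IntegerVector lab(n);
  const int *m = LOGICAL(mask);
  int *L = INTEGER(lab);
  int next = 0;
  std::queue<int> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!m[s] || L[s]) continue;
    ++next;
    L[s] = next;
    q.push((int)s);
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int x = c % nx, y = (c / nx) % ny, z = c / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            if (connectivity == 6 && std::abs(dx)+std::abs(dy)+std::abs(dz) != 1)
              continue;
            int xx = x+dx, yy = y+dy, zz = z+dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int j = idx3(xx, yy, zz, nx, ny);
            if (m[j] && !L[j]) { L[j] = next; q.push(j); }
          }
    }
  }
  lab.attr("dim") = d;
  return lab;
}

// Binary erosion/dilation with a full 3x3x3 (26-conn) or cross (6-conn) element.
// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, bool dilate, int connectivity) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  LogicalVector out(mask.size());
  const int *m = LOGICAL(mask);
  int *o = LOGICAL(out);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        bool hit = false, all = true;
        for (int dz = -1; dz <= 1 && (!hit || all); ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (connectivity == 6 &&
                  std::abs(dx)+std::abs(dy)+std::abs(dz) > 1) continue;
              int xx = x+dx, yy = y+dy, zz = z+dz;
              bool fg;
              if (xx < 0 || yy < 0 || zz < 0 ||
                  xx >= nx || yy >= ny || zz >= nz) fg = false;
              else fg = m[idx3(xx, yy, zz, nx, ny)] != 0;
              if (fg) hit = true; else all = false;
            }
        o[idx3(x, y, z, nx, ny)] = dilate ? hit : all;
      }
  out.attr("dim") = d;
  return out;
}

// Fill interior cavities: background connected to the volume border (6-conn)
// stays background, every other voxel becomes foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t n = mask.size();
  std::vector<char> outside(n, 0);
  const int *m = LOGICAL(mask);
  std::queue<int> q;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x && y && z && x != nx-1 && y != ny-1 && z != nz-1) continue;
        int j = idx3(x, y, z, nx, ny);
        if (!m[j] && !outside[j]) { outside[j] = 1; q.push(j); }
      }
  const int delta[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    int c = q.front(); q.pop();
    int x = c % nx, y = (c / nx) % ny, z = c / (nx * ny);
    for (int k = 0; k < 6; ++k) {
      int xx = x+delta[k][0], yy = y+delta[k][1], zz = z+delta[k][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      int j = idx3(xx, yy, zz, nx, ny);
      if (!m[j] && !outside[j]) { outside[j] = 1; q.push(j); }
    }
  }
  LogicalVector out(n);
  int *o = LOGICAL(out);
  for (R_xlen_t i = 0; i < n; ++i) o[i] = !outside[i];
  out.attr("dim") = d;
  return out;
}

// Boundary voxels: foreground with a 6-neighbour outside the mask (the volume
// edge counts as outside).
// [[Rcpp::export]]
LogicalVector cpp_boundary(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  LogicalVector out(mask.size());
  const int *m = LOGICAL(mask);
  int *o = LOGICAL(out);
  const int delta[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int j = idx3(x, y, z, nx, ny);
        if (!m[j]) { o[j] = 0; continue; }
        bool edge = false;
        for (int k = 0; k < 6 && !edge; ++k) {
          int xx = x+delta[k][0], yy = y+delta[k][1], zz = z+delta[k][2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            edge = true;
          else if (!m[idx3(xx, yy, zz, nx, ny)]) edge = true;
        }
        o[j] = edge;
      }
  out.attr("dim") = d;
  return out;
}

// Fraction of rows of A (n x 3 voxel coordinates) that lie within Euclidean
// distance `tol` of some row of B. Spatial hash on the integer grid.
// [[Rcpp::export]]
double cpp_match_fraction(NumericMatrix A, NumericMatrix B, double tol) {
  int nA = A.nrow(), nB = B.nrow();
  if (nA == 0) return 1.0;
  if (nB == 0) return 0.0;
  // hash B by integer cell
  std::vector<long long> keys(nB);
  std::vector<int> order(nB);
  auto key_of = [](long long x, long long y, long long z) {
    return ((x + 1024) << 42) | ((y + 1024) << 21) | (z + 1024);
  };
  for (int i = 0; i < nB; ++i)
    keys[i] = key_of((long long)std::llround(B(i,0)),
                     (long long)std::llround(B(i,1)),
                     (long long)std::llround(B(i,2)));
  // simple map
  std::vector<std::pair<long long,int> > table(nB);
  for (int i = 0; i < nB; ++i) table[i] = std::make_pair(keys[i], i);
  std::sort(table.begin(), table.end());
  int r = (int)std::ceil(tol);
  double tol2 = tol * tol;
  int matched = 0;
  for (int i = 0; i < nA; ++i) {
    double ax = A(i,0), ay = A(i,1), az = A(i,2);
    long long cx = (long long)std::llround(ax);
    long long cy = (long long)std::llround(ay);
    long long cz = (long long)std::llround(az);
    bool hit = false;
    for (long long dz = -r-1; dz <= r+1 && !hit; ++dz)
      for (long long dy = -r-1; dy <= r+1 && !hit; ++dy)
        for (long long dx = -r-1; dx <= r+1 && !hit; ++dx) {
          long long k = key_of(cx+dx, cy+dy, cz+dz);
          auto lo = std::lower_bound(table.begin(), table.end(),
                                     std::make_pair(k, -1));
          for (auto it = lo; it != table.end() && it->first == k; ++it) {
            int j = it->second;
            double ddx = B(j,0)-ax, ddy = B(j,1)-ay, ddz = B(j,2)-az;
            if (ddx*ddx + ddy*ddy + ddz*ddz <= tol2 + 1e-12) { hit = true; break; }
          }
        }
    if (hit) ++matched;
  }
  return (double)matched / nA;
}

// Multi-source BFS region growing: assigns every foreground voxel of `mask`
// the label of the nearest (BFS, 26-conn) nonzero marker. Marker-based split
// of touching components.
// [[Rcpp::export]]
IntegerVector cpp_grow_markers(LogicalVector mask, IntegerVector markers) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t n = mask.size();
  IntegerVector lab(n);
  const int *m = LOGICAL(mask);
  const int *mk = INTEGER(markers);
  int *L = INTEGER(lab);
  std::queue<int> q;
  for (R_xlen_t i = 0; i < n; ++i)
    if (m[i] && mk[i]) { L[i] = mk[i]; q.push((int)i); }
  while (!q.empty()) {
    int c = q.front(); q.pop();
    int x = c % nx, y = (c / nx) % ny, z = c / (nx * ny);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x+dx, yy = y+dy, zz = z+dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          int j = idx3(xx, yy, zz, nx, ny);
          if (m[j] && !L[j]) { L[j] = L[c]; q.push(j); }
        }
  }
  lab.attr("dim") = d;
  return lab;
}

// Separable Gaussian smoothing of a 3-D field (reflecting boundaries).
static void gauss1d(std::vector<double> &buf, std::vector<double> &tmp,
                    const std::vector<double> &ker) {
  int n = (int)buf.size(), r = (int)ker.size() / 2;
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int k = -r; k <= r; ++k) {
      int j = i + k;
      if (j < 0) j = -j - 1;
      if (j >= n) j = 2 * n - j - 1;
      acc += ker[k + r] * buf[j];
    }
    tmp[i] = acc;
  }
  buf.swap(tmp);
}

// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, double sigma) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  NumericVector out = clone(vol);
  if (sigma <= 0) return out;
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int k = -r; k <= r; ++k) {
    ker[k + r] = std::exp(-0.5 * k * k / (sigma * sigma));
    s += ker[k + r];
  }
  for (auto &w : ker) w /= s;
  double *v = REAL(out);
  std::vector<double> buf(std::max(nx, std::max(ny, nz)));
  std::vector<double> tmp(buf.size());
  // x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      buf.resize(nx); tmp.resize(nx);
      for (int x = 0; x < nx; ++x) buf[x] = v[idx3(x, y, z, nx, ny)];
      gauss1d(buf, tmp, ker);
      for (int x = 0; x < nx; ++x) v[idx3(x, y, z, nx, ny)] = buf[x];
    }
  // y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      buf.resize(ny); tmp.resize(ny);
      for (int y = 0; y < ny; ++y) buf[y] = v[idx3(x, y, z, nx, ny)];
      gauss1d(buf, tmp, ker);
      for (int y = 0; y < ny; ++y) v[idx3(x, y, z, nx, ny)] = buf[y];
    }
  // z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      buf.resize(nz); tmp.resize(nz);
      for (int z = 0; z < nz; ++z) buf[z] = v[idx3(x, y, z, nx, ny)];
      gauss1d(buf, tmp, ker);
      for (int z = 0; z < nz; ++z) v[idx3(x, y, z, nx, ny)] = buf[z];
    }
  return out;
}

static double corr_cc(const double *a, const double *b, R_xlen_t n) {
  double ma = 0, mb = 0;
  for (R_xlen_t i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sab = 0, saa = 0, sbb = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  if (saa <= 0 || sbb <= 0) return 0.0;
  return sab / std::sqrt(saa * sbb);
}

// Demons-style dense deformable registration of `moving` onto `fixed`
// (both already intensity-normalised). Displacement field in voxel units,
// pull-back convention: warped(v) = moving(v + u(v)). Convergence is
// monitored on the correlation coefficient between warped and fixed.
// Returns list(ux, uy, uz, cc, iterations).
// [[Rcpp::export]]
List cpp_demons(NumericVector fixedv, NumericVector moving, int max_iter,
                double tol, double sigma_field, double step_cap) {
  IntegerVector d = fixedv.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t n = fixedv.size();
  NumericVector ux(n), uy(n), uz(n);
  ux.attr("dim") = d; uy.attr("dim") = d; uz.attr("dim") = d;
  NumericVector warped(n);
  warped.attr("dim") = d;
  const double *f = REAL(fixedv);
  const double *m = REAL(moving);
  double *w = REAL(warped);
  double last_cc = -2.0, cc = -2.0;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    // warp
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int j = idx3(x, y, z, nx, ny);
          w[j] = sample_trilinear(m, nx, ny, nz,
                                  x + REAL(ux)[j], y + REAL(uy)[j],
                                  z + REAL(uz)[j]);
        }
    cc = corr_cc(w, f, n);
    if (it > 0 && std::fabs(cc - last_cc) < tol) break;
    last_cc = cc;
    // demons force from warped image gradient
    double *pux = REAL(ux), *puy = REAL(uy), *puz = REAL(uz);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int j = idx3(x, y, z, nx, ny);
          double gx = 0, gy = 0, gz = 0;
          if (x > 0 && x < nx-1)
            gx = 0.5 * (w[idx3(x+1,y,z,nx,ny)] - w[idx3(x-1,y,z,nx,ny)]);
          if (y > 0 && y < ny-1)
            gy = 0.5 * (w[idx3(x,y+1,z,nx,ny)] - w[idx3(x,y-1,z,nx,ny)]);
          if (z > 0 && z < nz-1)
            gz = 0.5 * (w[idx3(x,y,z+1,nx,ny)] - w[idx3(x,y,z-1,nx,ny)]);
          double diff = w[j] - f[j];
          double denom = gx*gx + gy*gy + gz*gz + diff*diff;
          if (denom < 1e-12) continue;
          double sx = -diff * gx / denom;
          double sy = -diff * gy / denom;
          double sz = -diff * gz / denom;
          double norm = std::sqrt(sx*sx + sy*sy + sz*sz);
          if (norm > step_cap) {
            sx *= step_cap / norm; sy *= step_cap / norm; sz *= step_cap / norm;
          }
          pux[j] += sx; puy[j] += sy; puz[j] += sz;
        }
    ux = cpp_gauss3(ux, sigma_field);
    uy = cpp_gauss3(uy, sigma_field);
    uz = cpp_gauss3(uz, sigma_field);
  }
  return List::create(_["ux"] = ux, _["uy"] = uy, _["uz"] = uz,
                      _["cc"] = cc, _["iterations"] = it);
}
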