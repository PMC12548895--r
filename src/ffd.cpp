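// Free-form-deformation kernels: cubic B-spline displacement fields on a
// regular control lattice, SSD registration cost with analytic gradient,
// and volume resampling/filtering primitives.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// cubic uniform B-spline basis, l = 0..3, u in [0,1)
static inline double bspl(int l, double u) {
  switch (l) {
  case 0: { double v = 1.0 - u; return v * v * v / 6.0; }
  case 1: return (3.0 * u * u * u - 6.0 * u * u + 4.0) / 6.0;
  case 2: return (-3.0 * u * u * u + 3.0 * u * u + 3.0 * u + 1.0) / 6.0;
  default: return u * u * u / 6.0;
  }
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Evaluate B-spline displacement at arbitrary (clamped) voxel coordinates.
// ctrl: nc x 3 matrix, lattice dims ncd = (ncx,ncy,ncz), spacing in voxels.
// Point p maps to lattice cell i0 = floor(p/spacing); uses ctrl[i0..i0+3].
// Lattice index 0 corresponds to control position -spacing (one-knot margin).
// [[Rcpp::export]]
NumericMatrix cpp_ffd_disp_points(NumericMatrix pts, NumericMatrix ctrl,
                                  IntegerVector ncd, double spacing,
                                  NumericVector domdim) {
  int n = pts.nrow();
  int ncx = ncd[0], ncy = ncd[1], ncz = ncd[2];
  NumericMatrix out(n, 3);
  for (int q = 0; q < n; ++q) {
    double p[3];
    // voxel centres sit at integer coordinates; the physical volume
    // extends half a voxel beyond the outermost centres
    for (int d = 0; d < 3; ++d)
      p[d] = clampd(pts(q, d), -0.5, domdim[d] - 0.5);
    double g[3]; int i0[3]; double u[3];
    for (int d = 0; d < 3; ++d) {
      g[d] = p[d] / spacing;
      i0[d] = (int)std::floor(g[d]);
      u[d] = g[d] - i0[d];
    }
    double wx[4], wy[4], wz[4];
    for (int l = 0; l < 4; ++l) {
      wx[l] = bspl(l, u[0]); wy[l] = bspl(l, u[1]); wz[l] = bspl(l, u[2]);
    }
    double acc[3] = {0.0, 0.0, 0.0};
    for (int lz = 0; lz < 4; ++lz) {
      int kz = i0[2] + lz; if (kz < 0) kz = 0; if (kz >= ncz) kz = ncz - 1;
      for (int ly = 0; ly < 4; ++ly) {
        int ky = i0[1] + ly; if (ky < 0) ky = 0; if (ky >= ncy) ky = ncy - 1;
        double wyz = wy[ly] * wz[lz];
        for (int lx = 0; lx < 4; ++lx) {
          int kx = i0[0] + lx; if (kx < 0) kx = 0; if (kx >= ncx) kx = ncx - 1;
          double w = wx[lx] * wyz;
          int ci = kx + ncx * (ky + ncy * kz);
          acc[0] += w * ctrl(ci, 0);
          acc[1] += w * ctrl(ci, 1);
          acc[2] += w * ctrl(ci, 2);
        }
      }
    }
    out(q, 0) = acc[0]; out(q, 1) = acc[1]; out(q, 2) = acc[2];
  }
  return out;
}

static inline double trilinear(const double* v, int nx, int ny, int nz,
                               double x, double y, double z) {
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  int x0 = (int)std::floor(x); if (x0 > nx - 2) x0 = nx - 2; if (nx == 1) x0 = 0;
  int y0 = (int)std::floor(y); if (y0 > ny - 2) y0 = ny - 2; if (ny == 1) y0 = 0;
  int z0 = (int)std::floor(z); if (z0 > nz - 2) z0 = nz - 2; if (nz == 1) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int x1 = nx == 1 ? x0 : x0 + 1, y1 = ny == 1 ? y0 : y0 + 1,
      z1 = nz == 1 ? z0 : z0 + 1;
  #define V(i,j,k) v[(i) + nx * ((j) + (size_t)ny * (k))]
  double c00 = V(x0,y0,z0) * (1-fx) + V(x1,y0,z0) * fx;
  double c10 = V(x0,y1,z0) * (1-fx) + V(x1,y1,z0) * fx;
  double c01 = V(x0,y0,z1) * (1-fx) + V(x1,y0,z1) * fx;
  double c11 = V(x0,y1,z1) * (1-fx) + V(x1,y1,z1) * fx;
  #undef V
  double c0 = c00 * (1-fy) + c10 * fy;
  double c1 = c01 * (1-fy) + c11 * fy;
  return c0 * (1-fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dims,
                                   NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double* v = REAL(vol);
  for (int q = 0; q < n; ++q)
    out[q] = trilinear(v, nx, ny, nz, pts(q, 0), pts(q, 1), pts(q, 2));
  return out;
}

// exact value + gradient of the trilinear interpolant at (x, y, z);
// partials are zeroed where the position is clamped to the boundary
static inline double trilinear_vg(const double* v, int nx, int ny, int nz,
                                  double x, double y, double z,
                                  double* gout) {
  bool cx = x <= 0.0 || x >= nx - 1.0;
  bool cy = y <= 0.0 || y >= ny - 1.0;
  bool cz = z <= 0.0 || z >= nz - 1.0;
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  int x0 = (int)std::floor(x); if (x0 > nx - 2) x0 = nx - 2; if (nx == 1) x0 = 0;
  int y0 = (int)std::floor(y); if (y0 > ny - 2) y0 = ny - 2; if (ny == 1) y0 = 0;
  int z0 = (int)std::floor(z); if (z0 > nz - 2) z0 = nz - 2; if (nz == 1) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int x1 = nx == 1 ? x0 : x0 + 1, y1 = ny == 1 ? y0 : y0 + 1,
      z1 = nz == 1 ? z0 : z0 + 1;
  #define V(i,j,k) v[(i) + nx * ((j) + (size_t)ny * (k))]
  double v000 = V(x0,y0,z0), v100 = V(x1,y0,z0);
  double v010 = V(x0,y1,z0), v110 = V(x1,y1,z0);
  double v001 = V(x0,y0,z1), v101 = V(x1,y0,z1);
  double v011 = V(x0,y1,z1), v111 = V(x1,y1,z1);
  #undef V
  double c00 = v000 * (1-fx) + v100 * fx;
  double c10 = v010 * (1-fx) + v110 * fx;
  double c01 = v001 * (1-fx) + v101 * fx;
  double c11 = v011 * (1-fx) + v111 * fx;
  double c0 = c00 * (1-fy) + c10 * fy;
  double c1 = c01 * (1-fy) + c11 * fy;
  double val = c0 * (1-fz) + c1 * fz;
  if (gout) {
    double dx00 = v100 - v000, dx10 = v110 - v010;
    double dx01 = v101 - v001, dx11 = v111 - v011;
    gout[0] = cx ? 0.0 : ((dx00 * (1-fy) + dx10 * fy) * (1-fz) +
                          (dx01 * (1-fy) + dx11 * fy) * fz);
    gout[1] = cy ? 0.0 : ((c10 - c00) * (1-fz) + (c11 - c01) * fz);
    gout[2] = cz ? 0.0 : (c1 - c0);
  }
  return val;
}

// SSD cost + gradient wrt control displacements for one resolution level.
// Cost = mean_x (ref(x) - mov(x+u(x)))^2
//      + lambda * mean_c |lap(c) / spacing^2|^2 (lattice bending surrogate;
//        the spacing^2 normalisation makes it lattice-resolution invariant).
// The image term uses the exact gradient of the trilinear interpolant so
// the objective and gradient are mutually consistent.
// with_grad = false skips the gradient scatter (cheap line-search evals).
// [[Rcpp::export]]
List cpp_ffd_cost_grad(NumericVector ref, NumericVector mov,
                       IntegerVector dims, NumericMatrix ctrl,
                       IntegerVector ncd, double spacing, double lambda,
                       bool with_grad = true) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ncx = ncd[0], ncy = ncd[1], ncz = ncd[2];
  size_t nvox = (size_t)nx * ny * nz;
  int nc = ncx * ncy * ncz;
  NumericMatrix grad(nc, 3);
  const double* rp = REAL(ref); const double* mp = REAL(mov);

  // per-axis basis weights are separable and periodic in the fractional
  // part; cache them per x-index (and y,z) since the lattice is regular
  std::vector<double> wxs(4 * nx), wys(4 * ny), wzs(4 * nz);
  std::vector<int> ixs(nx), iys(ny), izs(nz);
  for (int x = 0; x < nx; ++x) {
    double gxx = x / spacing; int i0 = (int)std::floor(gxx); double u = gxx - i0;
    ixs[x] = i0; for (int l = 0; l < 4; ++l) wxs[4 * x + l] = bspl(l, u);
  }
  for (int y = 0; y < ny; ++y) {
    double gyy = y / spacing; int i0 = (int)std::floor(gyy); double u = gyy - i0;
    iys[y] = i0; for (int l = 0; l < 4; ++l) wys[4 * y + l] = bspl(l, u);
  }
  for (int z = 0; z < nz; ++z) {
    double gzz = z / spacing; int i0 = (int)std::floor(gzz); double u = gzz - i0;
    izs[z] = i0; for (int l = 0; l < 4; ++l) wzs[4 * z + l] = bspl(l, u);
  }

  double ssd = 0.0;
  size_t idx = 0;
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x, ++idx) {
        // displacement at voxel
        double ux = 0, uy = 0, uz = 0;
        for (int lz = 0; lz < 4; ++lz) {
          int kz = izs[z] + lz; if (kz < 0) kz = 0; if (kz >= ncz) kz = ncz - 1;
          double wz_ = wzs[4 * z + lz];
          for (int ly = 0; ly < 4; ++ly) {
            int ky = iys[y] + ly; if (ky < 0) ky = 0; if (ky >= ncy) ky = ncy - 1;
            double wyz = wys[4 * y + ly] * wz_;
            int base = ncx * (ky + ncy * kz);
            for (int lx = 0; lx < 4; ++lx) {
              int kx = ixs[x] + lx; if (kx < 0) kx = 0; if (kx >= ncx) kx = ncx - 1;
              double w = wxs[4 * x + lx] * wyz;
              int ci = kx + base;
              ux += w * ctrl(ci, 0); uy += w * ctrl(ci, 1); uz += w * ctrl(ci, 2);
            }
          }
        }
        double px = x + ux, py = y + uy, pz = z + uz;
        double mg[3];
        double mval = trilinear_vg(mp, nx, ny, nz, px, py, pz,
                                   with_grad ? mg : (double*)0);
        double r = rp[idx] - mval;
        ssd += r * r;
        if (!with_grad) continue;
        // d cost / d u = -2 r * d mov(T x) / d u / nvox
        double fac = -2.0 * r / (double)nvox;
        double dx = fac * mg[0], dy = fac * mg[1], dz = fac * mg[2];
        for (int lz = 0; lz < 4; ++lz) {
          int kz = izs[z] + lz; if (kz < 0) kz = 0; if (kz >= ncz) kz = ncz - 1;
          double wz_ = wzs[4 * z + lz];
          for (int ly = 0; ly < 4; ++ly) {
            int ky = iys[y] + ly; if (ky < 0) ky = 0; if (ky >= ncy) ky = ncy - 1;
            double wyz = wys[4 * y + ly] * wz_;
            int base = ncx * (ky + ncy * kz);
            for (int lx = 0; lx < 4; ++lx) {
              int kx = ixs[x] + lx; if (kx < 0) kx = 0; if (kx >= ncx) kx = ncx - 1;
              double w = wxs[4 * x + lx] * wyz;
              int ci = kx + base;
              grad(ci, 0) += w * dx; grad(ci, 1) += w * dy; grad(ci, 2) += w * dz;
            }
          }
        }
      }
    }
  }
  double cost = ssd / (double)nvox;

  // regularizer: mean squared lattice Laplacian of control displacements,
  // normalised by spacing^2 (discrete bending curvature)
  if (lambda > 0.0) {
    double inv_sp2 = 1.0 / (spacing * spacing);
    std::vector<double> lap(nc * 3, 0.0);
    double ereg = 0.0;
    for (int kz = 0; kz < ncz; ++kz)
      for (int ky = 0; ky < ncy; ++ky)
        for (int kx = 0; kx < ncx; ++kx) {
          int ci = kx + ncx * (ky + ncy * kz);
          for (int d = 0; d < 3; ++d) {
            double c = ctrl(ci, d), s = 0.0; int nn = 0;
            if (kx > 0)      { s += ctrl(ci - 1, d); ++nn; }
            if (kx < ncx - 1){ s += ctrl(ci + 1, d); ++nn; }
            if (ky > 0)      { s += ctrl(ci - ncx, d); ++nn; }
            if (ky < ncy - 1){ s += ctrl(ci + ncx, d); ++nn; }
            if (kz > 0)      { s += ctrl(ci - ncx * ncy, d); ++nn; }
            if (kz < ncz - 1){ s += ctrl(ci + ncx * ncy, d); ++nn; }
            double L = (s - nn * c) * inv_sp2;
            lap[ci + (size_t)nc * d] = L;
            ereg += L * L;
          }
        }
    ereg /= (double)nc;
    cost += lambda * ereg;
    // gradient of ereg: 2/nc * Laplacian(lap) (the stencil is self-adjoint)
    if (with_grad)
    for (int kz = 0; kz < ncz; ++kz)
      for (int ky = 0; ky < ncy; ++ky)
        for (int kx = 0; kx < ncx; ++kx) {
          int ci = kx + ncx * (ky + ncy * kz);
          for (int d = 0; d < 3; ++d) {
            size_t off = (size_t)nc * d;
            double c = lap[ci + off], s = 0.0; int nn = 0;
            if (kx > 0)      { s += lap[ci - 1 + off]; ++nn; }
            if (kx < ncx - 1){ s += lap[ci + 1 + off]; ++nn; }
            if (ky > 0)      { s += lap[ci - ncx + off]; ++nn; }
            if (ky < ncy - 1){ s += lap[ci + ncx + off]; ++nn; }
            if (kz > 0)      { s += lap[ci - ncx * ncy + off]; ++nn; }
            if (kz < ncz - 1){ s += lap[ci + ncx * ncy + off]; ++nn; }
            grad(ci, d) += lambda * 2.0 / (double)nc * inv_sp2 * (s - nn * c);
          }
        }
  }
  return List::create(_["cost"] = cost, _["grad"] = grad);
}

// central-difference gradient of a volume, one component per call
// [[Rcpp::export]]
NumericVector cpp_gradient3(NumericVector vol, IntegerVector dims, int axis) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(vol.size());
  const double* v = REAL(vol);
  double* o = REAL(out);
  size_t idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        int xm = x, xp = x, ym = y, yp = y, zm = z, zp = z;
        double h = 2.0;
        if (axis == 0) { xm = x > 0 ? x - 1 : 0; xp = x < nx-1 ? x + 1 : nx-1; h = xp - xm; }
        if (axis == 1) { ym = y > 0 ? y - 1 : 0; yp = y < ny-1 ? y + 1 : ny-1; h = yp - ym; }
        if (axis == 2) { zm = z > 0 ? z - 1 : 0; zp = z < nz-1 ? z + 1 : nz-1; h = zp - zm; }
        if (h == 0) { o[idx] = 0; continue; }
        size_t ip = xp + nx * ((size_t)yp + ny * zp);
        size_t im = xm + nx * ((size_t)ym + ny * zm);
        o[idx] = (v[ip] - v[im]) / h;
      }
  return out;
}

// Catmull-Rom kernel for cubic resampling
static inline double catrom(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 1.5 * t * t * t - 2.5 * t * t + 1.0;
  if (t < 2.0) return -0.5 * t * t * t + 2.5 * t * t - 4.0 * t + 2.0;
  return 0.0;
}

// resize a 3D volume; method 0 = nearest, 1 = trilinear, 2 = cubic
// [[Rcpp::export]]
NumericVector cpp_resize3(NumericVector vol, IntegerVector dims,
                          IntegerVector newdims, int method) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int mx = newdims[0], my = newdims[1], mz = newdims[2];
  NumericVector out((size_t)mx * my * mz);
  const double* v = REAL(vol);
  double* o = REAL(out);
  double sx = (double)nx / mx, sy = (double)ny / my, sz = (double)nz / mz;
  size_t idx = 0;
  for (int z = 0; z < mz; ++z)
    for (int y = 0; y < my; ++y)
      for (int x = 0; x < mx; ++x, ++idx) {
        // map output voxel center to input coordinates
        double px = (x + 0.5) * sx - 0.5;
        double py = (y + 0.5) * sy - 0.5;
        double pz = (z + 0.5) * sz - 0.5;
        if (method == 0) {
          int ix = (int)std::lround(px), iy = (int)std::lround(py),
              iz = (int)std::lround(pz);
          ix = ix < 0 ? 0 : (ix > nx-1 ? nx-1 : ix);
          iy = iy < 0 ? 0 : (iy > ny-1 ? ny-1 : iy);
          iz = iz < 0 ? 0 : (iz > nz-1 ? nz-1 : iz);
          o[idx] = v[ix + nx * ((size_t)iy + ny * iz)];
        } else if (method == 1) {
          o[idx] = trilinear(v, nx, ny, nz, px, py, pz);
        } else {
          px = clampd(px, 0.0, nx - 1.0); py = clampd(py, 0.0, ny - 1.0);
          pz = clampd(pz, 0.0, nz - 1.0);
          int x0 = (int)std::floor(px), y0 = (int)std::floor(py),
              z0 = (int)std::floor(pz);
          double acc = 0.0, wsum = 0.0;
          for (int dz2 = -1; dz2 <= 2; ++dz2) {
            int zz = z0 + dz2; if (zz < 0) zz = 0; if (zz > nz-1) zz = nz-1;
            double wz = catrom(pz - (z0 + dz2));
            for (int dy2 = -1; dy2 <= 2; ++dy2) {
              int yy = y0 + dy2; if (yy < 0) yy = 0; if (yy > ny-1) yy = ny-1;
              double wy = catrom(py - (y0 + dy2)) * wz;
              for (int dx2 = -1; dx2 <= 2; ++dx2) {
                int xx = x0 + dx2; if (xx < 0) xx = 0; if (xx > nx-1) xx = nx-1;
                double w = catrom(px - (x0 + dx2)) * wy;
                acc += w * v[xx + nx * ((size_t)yy + ny * zz)];
                wsum += w;
              }
            }
          }
          o[idx] = wsum != 0 ? acc / wsum : 0.0;
        }
      }
  return out;
}

// separable Gaussian filter, truncated at ceil(3*sigma), reflect padding
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector dims, double sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  if (sigma <= 0) return clone(vol);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto& w : k) w /= s;
  NumericVector a = clone(vol);
  NumericVector b((size_t)nx * ny * nz);
  double* ap = REAL(a); double* bp = REAL(b);
  int n[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    size_t idx = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++idx) {
          int c[3] = {x, y, z};
          double acc = 0;
          for (int i = -r; i <= r; ++i) {
            int cc = c[axis] + i;
            // reflect
            if (cc < 0) cc = -cc - 1;
            if (cc > n[axis] - 1) cc = 2 * n[axis] - 1 - cc;
            if (cc < 0) cc = 0; if (cc > n[axis] - 1) cc = n[axis] - 1;
            int p[3] = {x, y, z}; p[axis] = cc;
            acc += k[i + r] * ap[p[0] + nx * ((size_t)p[1] + ny * p[2])];
          }
          bp[idx] = acc;
        }
    std::swap(ap, bp);
  }
  // after 3 passes result is in ap; figure out which vector that is
  if (ap == REAL(a)) return a; else return b;
}
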