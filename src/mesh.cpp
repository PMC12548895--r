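// Mesh/volume kernels: marching-tetrahedra isosurface extraction,
// parity-fill voxelization of closed meshes, brute-force nearest
// neighbours, Gaussian splatting and surface shell masks.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// ---- marching tetrahedra -------------------------------------------------

struct MTState {
  std::unordered_map<uint64_t, int> edgeVert;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

static int edge_vertex(MTState& st, uint64_t ia, uint64_t ib,
                       const double* pa, const double* pb,
                       double fa, double fb, double iso) {
  uint64_t key = ia < ib ? (ia << 32 | ib) : (ib << 32 | ia);
  auto it = st.edgeVert.find(key);
  if (it != st.edgeVert.end()) return it->second;
  double t = (iso - fa) / (fb - fa);
  if (t < 0) t = 0; if (t > 1) t = 1;
  st.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  st.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  st.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  int id = (int)st.vx.size() - 1;
  st.edgeVert[key] = id;
  return id;
}

// append triangle (a,b,c), flipping if needed so the normal points away
// from the "inside" witness point w
static void add_tri(MTState& st, int a, int b, int c, const double* w) {
  double ax = st.vx[a], ay = st.vy[a], az = st.vz[a];
  double ux = st.vx[b] - ax, uy = st.vy[b] - ay, uz = st.vz[b] - az;
  double vx_ = st.vx[c] - ax, vy_ = st.vy[c] - ay, vz_ = st.vz[c] - az;
  double nx = uy * vz_ - uz * vy_;
  double ny = uz * vx_ - ux * vz_;
  double nz = ux * vy_ - uy * vx_;
  double cx = (ax + st.vx[b] + st.vx[c]) / 3.0 - w[0];
  double cy = (ay + st.vy[b] + st.vy[c]) / 3.0 - w[1];
  double cz = (az + st.vz[b] + st.vz[c]) / 3.0 - w[2];
  if (nx * cx + ny * cy + nz * cz < 0) std::swap(b, c);
  st.f0.push_back(a); st.f1.push_back(b); st.f2.push_back(c);
}

// [[Rcpp::export]]
List cpp_march_tets(NumericVector vol, IntegerVector dims, double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* v = REAL(vol);
  MTState st;
  // 6 tetrahedra per cube sharing the 0-6 diagonal
  const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};
  const int cornOff[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        double f[8]; uint64_t gi[8]; double P[8][3];
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          int cx = x + cornOff[c][0], cy = y + cornOff[c][1],
              cz = z + cornOff[c][2];
          gi[c] = cx + (uint64_t)nx * (cy + (uint64_t)ny * cz);
          f[c] = v[gi[c]];
          P[c][0] = cx; P[c][1] = cy; P[c][2] = cz;
          if (f[c] > iso) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int in[4], nin = 0, out[4], nout = 0;
          for (int a = 0; a < 4; ++a) {
            if (f[vi[a]] > iso) in[nin++] = vi[a]; else out[nout++] = vi[a];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int apex = nin == 1 ? in[0] : out[0];
            int others[3]; int k = 0;
            for (int a = 0; a < 4; ++a) if (vi[a] != apex) others[k++] = vi[a];
            int e[3];
            for (int a = 0; a < 3; ++a)
              e[a] = edge_vertex(st, gi[apex], gi[others[a]], P[apex],
                                 P[others[a]], f[apex], f[others[a]], iso);
            // witness: a point strictly inside (field > iso)
            const double* w = nin == 1 ? P[in[0]] : P[in[0]];
            add_tri(st, e[0], e[1], e[2], w);
          } else { // 2 in, 2 out -> quad
            int a0 = in[0], a1 = in[1], b0 = out[0], b1 = out[1];
            int e00 = edge_vertex(st, gi[a0], gi[b0], P[a0], P[b0], f[a0], f[b0], iso);
            int e01 = edge_vertex(st, gi[a0], gi[b1], P[a0], P[b1], f[a0], f[b1], iso);
            int e10 = edge_vertex(st, gi[a1], gi[b0], P[a1], P[b0], f[a1], f[b0], iso);
            int e11 = edge_vertex(st, gi[a1], gi[b1], P[a1], P[b1], f[a1], f[b1], iso);
            double w[3] = {(P[a0][0] + P[a1][0]) / 2.0,
                           (P[a0][1] + P[a1][1]) / 2.0,
                           (P[a0][2] + P[a1][2]) / 2.0};
            add_tri(st, e00, e01, e11, w);
            add_tri(st, e00, e11, e10, w);
          }
        }
      }
  int nv = (int)st.vx.size(), nf = (int)st.f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i];
  }
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = st.f0[i] + 1; F(i, 1) = st.f1[i] + 1; F(i, 2) = st.f2[i] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---- voxelization --------------------------------------------------------

// parity fill along z columns; vertices in voxel coordinates
// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix V, IntegerMatrix F,
                           IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<std::vector<double>> cross((size_t)nx * ny);
  int nf = F.nrow();
  const double ex = 1e-4, ey = 1e-4 * std::sqrt(2.0); // break edge ties
  for (int t = 0; t < nf; ++t) {
    int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    double x1 = V(a,0), y1 = V(a,1), z1 = V(a,2);
    double x2 = V(b,0), y2 = V(b,1), z2 = V(b,2);
    double x3 = V(c,0), y3 = V(c,1), z3 = V(c,2);
    int xmin = (int)std::ceil(std::min({x1,x2,x3}) - ex);
    int xmax = (int)std::floor(std::max({x1,x2,x3}) + ex);
    int ymin = (int)std::ceil(std::min({y1,y2,y3}) - ey);
    int ymax = (int)std::floor(std::max({y1,y2,y3}) + ey);
    if (xmin < 0) xmin = 0; if (xmax > nx - 1) xmax = nx - 1;
    if (ymin < 0) ymin = 0; if (ymax > ny - 1) ymax = ny - 1;
    double det = (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1);
    if (std::fabs(det) < 1e-14) continue; // triangle vertical in z
    for (int yy = ymin; yy <= ymax; ++yy)
      for (int xx = xmin; xx <= xmax; ++xx) {
        double px = xx + ex, py = yy + ey;
        double l1 = ((x2 - px) * (y3 - py) - (x3 - px) * (y2 - py)) / det;
        double l2 = ((x3 - px) * (y1 - py) - (x1 - px) * (y3 - py)) / det;
        double l3 = 1.0 - l1 - l2;
        if (l1 < 0 || l2 < 0 || l3 < 0) continue;
        double zc = l1 * z1 + l2 * z2 + l3 * z3;
        cross[xx + (size_t)nx * yy].push_back(zc);
      }
  }
  LogicalVector out((size_t)nx * ny * nz);
  for (int yy = 0; yy < ny; ++yy)
    for (int xx = 0; xx < nx; ++xx) {
      auto& cs = cross[xx + (size_t)nx * yy];
      if (cs.empty()) continue;
      std::sort(cs.begin(), cs.end());
      for (size_t i = 0; i + 1 < cs.size(); i += 2) {
        int z0 = (int)std::ceil(cs[i]), z1 = (int)std::floor(cs[i + 1]);
        if (z0 < 0) z0 = 0; if (z1 > nz - 1) z1 = nz - 1;
        for (int zz = z0; zz <= z1; ++zz)
          out[xx + (size_t)nx * (yy + (size_t)ny * zz)] = true;
      }
    }
  return out;
}

// ---- nearest neighbours --------------------------------------------------

// for each query row, index (1-based) and distance of nearest target row
// [[Rcpp::export]]
List cpp_nn(NumericMatrix query, NumericMatrix target) {
  int n = query.nrow(), m = target.nrow(), d = query.ncol();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf; int bj = 0;
    for (int j = 0; j < m; ++j) {
      double s = 0;
      for (int k = 0; k < d; ++k) {
        double df = query(i, k) - target(j, k);
        s += df * df;
      }
      if (s < best) { best = s; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// squared pairwise distances (n x m), for small point sets (EM registration)
// [[Rcpp::export]]
NumericMatrix cpp_pdist2(NumericMatrix A, NumericMatrix B) {
  int n = A.nrow(), m = B.nrow(), d = A.ncol();
  NumericMatrix D(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double s = 0;
      for (int k = 0; k < d; ++k) {
        double df = A(i, k) - B(j, k);
        s += df * df;
      }
      D(i, j) = s;
    }
  return D;
}

// ---- rendering helpers ---------------------------------------------------

// sum of Gaussians at pts (voxel coords) with per-point amplitude
// [[Rcpp::export]]
NumericVector cpp_splat_gauss(IntegerVector dims, NumericMatrix pts,
                              NumericVector amp, double sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((size_t)nx * ny * nz);
  double* o = REAL(out);
  int r = (int)std::ceil(3.0 * sigma);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int p = 0; p < pts.nrow(); ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2), a = amp[p];
    int x0 = std::max(0, (int)std::floor(px) - r),
        x1 = std::min(nx - 1, (int)std::ceil(px) + r);
    int y0 = std::max(0, (int)std::floor(py) - r),
        y1 = std::min(ny - 1, (int)std::ceil(py) + r);
    int z0 = std::max(0, (int)std::floor(pz) - r),
        z1 = std::min(nz - 1, (int)std::ceil(pz) + r);
    for (int zz = z0; zz <= z1; ++zz)
      for (int yy = y0; yy <= y1; ++yy)
        for (int xx = x0; xx <= x1; ++xx) {
          double d2 = (xx - px) * (xx - px) + (yy - py) * (yy - py) +
                      (zz - pz) * (zz - pz);
          o[xx + (size_t)nx * (yy + (size_t)ny * zz)] += a * std::exp(-d2 * inv2s2);
        }
  }
  return out;
}

// voxels within `radius` of any point (surface shell mask)
// [[Rcpp::export]]
LogicalVector cpp_shell_mask(IntegerVector dims, NumericMatrix pts,
                             double radius) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((size_t)nx * ny * nz);
  int r = (int)std::ceil(radius);
  double r2 = radius * radius;
  for (int p = 0; p < pts.nrow(); ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    int x0 = std::max(0, (int)std::floor(px) - r),
        x1 = std::min(nx - 1, (int)std::ceil(px) + r);
    int y0 = std::max(0, (int)std::floor(py) - r),
        y1 = std::min(ny - 1, (int)std::ceil(py) + r);
    int z0 = std::max(0, (int)std::floor(pz) - r),
        z1 = std::min(nz - 1, (int)std::ceil(pz) + r);
    for (int zz = z0; zz <= z1; ++zz)
      for (int yy = y0; yy <= y1; ++yy)
        for (int xx = x0; xx <= x1; ++xx) {
          double d2 = (xx - px) * (xx - px) + (yy - py) * (yy - py) +
                      (zz - pz) * (zz - pz);
          if (d2 <= r2)
            out[xx + (size_t)nx * (yy + (size_t)ny * zz)] = true;
        }
  }
  return out;
}
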