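// 6-connected flood fill of background from the volume border,
// used for cavity detection in binary masks.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
LogicalVector cpp_flood_background(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> vis(n, 0);
  std::vector<size_t> stack;
  const int* m = LOGICAL(mask);
  auto push = [&](int x, int y, int z) {
    size_t i = x + (size_t)nx * (y + (size_t)ny * z);
    if (!vis[i] && !m[i]) { vis[i] = 1; stack.push_back(i); }
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        if (x == 0 || y == 0 || z == 0 || x == nx - 1 || y == ny - 1 ||
            z == nz - 1)
          push(x, y, z);
  while (!stack.empty()) {
    size_t i = stack.back(); stack.pop_back();
    int x = i % nx, y = (i / nx) % ny, z = i / ((size_t)nx * ny);
    if (x > 0) push(x - 1, y, z);
    if (x < nx - 1) push(x + 1, y, z);
    if (y > 0) push(x, y - 1, z);
    if (y < ny - 1) push(x, y + 1, z);
    if (z > 0) push(x, y, z - 1);
    if (z < nz - 1) push(x, y, z + 1);
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = vis[i] != 0;
  return out;
}

// 6-connected component labelling of the foreground
// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  const int* m = LOGICAL(mask);
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!m[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t i = stack.back(); stack.pop_back();
      int x = i % nx, y = (i / nx) % ny, z = i / ((size_t)nx * ny);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        size_t j = xx + (size_t)nx * (yy + (size_t)ny * zz);
        if (m[j] && !lab[j]) { lab[j] = cur; stack.push_back(j); }
      }
    }
  }
  lab.attr("n") = cur;
  return lab;
}
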