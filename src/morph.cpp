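#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

// 1D squared-distance transform (lower envelope of parabolas), samples at
// positions i*w.  Felzenszwalb & Huttenlocher.
static void dt1d(std::vector<double>& f, int n, double w) {
  if (n <= 0) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Euclidean distance (mm) from every voxel to the nearest TRUE voxel of a
// 3D mask on an anisotropic grid.  Voxels inside the mask get 0.
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // large finite sentinel: Inf breaks the parabola intersections (Inf-Inf)
  const double INF = 1e15;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

  std::vector<double> line;
  // x lines
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      bool any = false;
      for (int x = 0; x < nx; ++x) { line[x] = g[base + x]; if (line[x] < INF) any = true; }
      if (!any) continue;
      dt1d(line, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) g[base + x] = line[x];
    }
  // y lines
  line.assign(ny, 0.0);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      bool any = false;
      for (int y = 0; y < ny; ++y) { line[y] = g[base + (R_xlen_t)y * nx]; if (line[y] < INF) any = true; }
      if (!any) continue;
      dt1d(line, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)y * nx] = line[y];
    }
  // z lines
  line.assign(nz, 0.0);
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      bool any = false;
      for (int z = 0; z < nz; ++z) { line[z] = g[base + (R_xlen_t)z * nxy]; if (line[z] < INF) any = true; }
      if (!any) continue;
      dt1d(line, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) g[base + (R_xlen_t)z * nxy] = line[z];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] >= 1e14) ? R_PosInf : std::sqrt(g[i]);
  return out;
}

// 6-connected component labelling of a 3D mask; labels 1..K assigned in
// raster order of each component's first voxel (deterministic), 0 = off.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxy * nz;
  IntegerVector lab(n);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t i = q.front(); q.pop();
      int z = (int)(i / nxy);
      R_xlen_t r = i % nxy;
      int y = (int)(r / nx);
      int x = (int)(r % nx);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t j = (R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx;
        if (mask[j] && !lab[j]) { lab[j] = next; q.push(j); }
      }
    }
  }
  return lab;
}
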