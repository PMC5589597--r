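#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Siddon-style exact line integral of a voxelized density along the segment
// from u0 to u1 (continuous 0-based voxel-index coordinates; voxel (i,j,k)
// spans [i-0.5, i+0.5) etc.).  phys_len is the physical segment length in
// mm; the return value is the water-equivalent length in mm
// (sum of density * traversed physical length).  Density outside the grid
// counts as 0 (air).
static double ray_wepl_idx(const double* dens, const int nx, const int ny,
                           const int nz, const double u0[3],
                           const double u1[3], const double phys_len) {
  double du[3], tmin = 0.0, tmax = 1.0;
  const double lo[3] = {-0.5, -0.5, -0.5};
  const double hi[3] = {nx - 0.5, ny - 0.5, nz - 0.5};
  for (int a = 0; a < 3; ++a) {
    du[a] = u1[a] - u0[a];
    if (std::fabs(du[a]) < 1e-12) {
      if (u0[a] < lo[a] || u0[a] >= hi[a]) return 0.0;
    } else {
      double t1 = (lo[a] - u0[a]) / du[a];
      double t2 = (hi[a] - u0[a]) / du[a];
      if (t1 > t2) std::swap(t1, t2);
      tmin = std::max(tmin, t1);
      tmax = std::min(tmax, t2);
    }
  }
  if (tmin >= tmax) return 0.0;

  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  double wepl = 0.0, t = tmin;
  // next boundary-crossing parameter per axis
  double tnext[3], tstep[3];
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(du[a]) < 1e-12) {
      tnext[a] = R_PosInf;
      tstep[a] = R_PosInf;
    } else {
      tstep[a] = 1.0 / std::fabs(du[a]);
      double u = u0[a] + t * du[a];
      double b = (du[a] > 0) ? (std::floor(u + 0.5) + 0.5)
                             : (std::floor(u + 0.5) - 0.5);
      tnext[a] = (b - u0[a]) / du[a];
      if (tnext[a] <= t + 1e-14) tnext[a] += tstep[a];
    }
  }
  int guard = 4 * (nx + ny + nz) + 16;
  while (t < tmax - 1e-14 && guard-- > 0) {
    double tn = std::min({tnext[0], tnext[1], tnext[2], tmax});
    double tm = 0.5 * (t + tn);
    int i = (int)std::floor(u0[0] + tm * du[0] + 0.5);
    int j = (int)std::floor(u0[1] + tm * du[1] + 0.5);
    int k = (int)std::floor(u0[2] + tm * du[2] + 0.5);
    if (i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz)
      wepl += dens[(R_xlen_t)k * nxy + (R_xlen_t)j * nx + i] * (tn - t);
    for (int a = 0; a < 3; ++a)
      if (tnext[a] <= tn + 1e-14) tnext[a] += tstep[a];
    t = tn;
  }
  return wepl * phys_len;
}

static void phys_to_idx(const double x[3], const double origin[3],
                        const double* dirT, const double spacing[3],
                        double u[3]) {
  // u = (D^T (x - origin)) / spacing ; dirT stored column-major 3x3 of D
  double d[3] = {x[0] - origin[0], x[1] - origin[1], x[2] - origin[2]};
  for (int a = 0; a < 3; ++a) {
    // column a of D dotted with d (D^T row a)
    u[a] = (dirT[a * 3 + 0] * d[0] + dirT[a * 3 + 1] * d[1] +
            dirT[a * 3 + 2] * d[2]) / spacing[a];
  }
}

// [[Rcpp::export(name = ".ray_wepl_cpp")]]
double ray_wepl_cpp(NumericVector dens, IntegerVector dim,
                    NumericVector spacing, NumericVector origin,
                    NumericMatrix direction, NumericVector p0,
                    NumericVector p1) {
  double o[3] = {origin[0], origin[1], origin[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double dirT[9];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) dirT[c * 3 + r] = direction(r, c);
  double a[3] = {p0[0], p0[1], p0[2]}, b[3] = {p1[0], p1[1], p1[2]};
  double u0[3], u1[3];
  phys_to_idx(a, o, dirT, sp, u0);
  phys_to_idx(b, o, dirT, sp, u1);
  double len = std::sqrt((b[0] - a[0]) * (b[0] - a[0]) +
                         (b[1] - a[1]) * (b[1] - a[1]) +
                         (b[2] - a[2]) * (b[2] - a[2]));
  return ray_wepl_idx(REAL(dens), dim[0], dim[1], dim[2], u0, u1, len);
}

static inline double smooth_aperture(double u, double half, double sigma) {
  const double s = sigma * M_SQRT2;
  return 0.5 * (std::erf((half - u) / s) + std::erf((half + u) / s));
}

// Primary-photon beam dose on every voxel of a density grid:
//   D = weight * exp(-mu * wepl) * (SAD/r)^2 * f_lateral
// with wepl the Siddon line integral source->voxel (converted to cm via
// mu given per mm here), r the source distance, f_lateral a Gaussian-
// smoothed square aperture projected to the isocenter plane.
// [[Rcpp::export(name = ".beam_dose_cpp")]]
NumericVector beam_dose_cpp(NumericVector dens, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix direction, NumericVector src,
                            NumericVector e1, NumericVector e2,
                            NumericVector e3, double sad, double half_field,
                            double sigma, double mu_per_mm, double weight,
                            bool inv_square, bool penumbra) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  double o[3] = {origin[0], origin[1], origin[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double dirT[9];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) dirT[c * 3 + r] = direction(r, c);
  double s0[3] = {src[0], src[1], src[2]};
  double u_src[3];
  phys_to_idx(s0, o, dirT, sp, u_src);
  const double* dd = REAL(dens);
  double* po = REAL(out);

  R_xlen_t i = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++i) {
        // physical voxel center: origin + D (spacing * idx)
        double vx = sp[0] * x, vy = sp[1] * y, vz = sp[2] * z;
        double px = o[0] + direction(0, 0) * vx + direction(0, 1) * vy +
                    direction(0, 2) * vz;
        double py = o[1] + direction(1, 0) * vx + direction(1, 1) * vy +
                    direction(1, 2) * vz;
        double pz = o[2] + direction(2, 0) * vx + direction(2, 1) * vy +
                    direction(2, 2) * vz;
        double dx = px - s0[0], dy = py - s0[1], dz = pz - s0[2];
        double zeta = dx * e3[0] + dy * e3[1] + dz * e3[2];
        if (zeta < 1.0) { po[i] = 0.0; continue; }  // at/behind source
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        double lu = (dx * e1[0] + dy * e1[1] + dz * e1[2]) * sad / zeta;
        double lv = (dx * e2[0] + dy * e2[1] + dz * e2[2]) * sad / zeta;
        double f;
        if (penumbra)
          f = smooth_aperture(lu, half_field, sigma) *
              smooth_aperture(lv, half_field, sigma);
        else
          f = (std::fabs(lu) <= half_field && std::fabs(lv) <= half_field)
                  ? 1.0 : 0.0;
        if (f < 1e-9) { po[i] = 0.0; continue; }
        double u1[3];
        double p[3] = {px, py, pz};
        phys_to_idx(p, o, dirT, sp, u1);
        double wepl = ray_wepl_idx(dd, nx, ny, nz, u_src, u1, r);
        double dose = weight * std::exp(-mu_per_mm * wepl) * f;
        if (inv_square) dose *= (sad / r) * (sad / r);
        po[i] = dose;
      }
  return out;
}
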