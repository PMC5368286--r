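#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double tri(const double* v, const int* d, double x, double y,
                         double z, double fill) {
  if (x < 0 || y < 0 || z < 0 || x > d[0] - 1 || y > d[1] - 1 ||
      z > d[2] - 1) return fill;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 >= d[0] - 1) i0 = d[0] - 2; if (i0 < 0) i0 = 0;
  if (j0 >= d[1] - 1) j0 = d[1] - 2; if (j0 < 0) j0 = 0;
  if (k0 >= d[2] - 1) k0 = d[2] - 2; if (k0 < 0) k0 = 0;
  double tx = x - i0, ty = y - j0, tz = z - k0;
  const long nx = d[0], nxy = (long)d[0] * d[1];
  const double* p = v + i0 + nx * j0 + nxy * k0;
  double c00 = p[0] * (1 - tx) + p[1] * tx;
  double c10 = p[nx] * (1 - tx) + p[nx + 1] * tx;
  double c01 = p[nxy] * (1 - tx) + p[nxy + 1] * tx;
  double c11 = p[nx + nxy] * (1 - tx) + p[nx + nxy + 1] * tx;
  double c0 = c00 * (1 - ty) + c10 * ty;
  double c1 = c01 * (1 - ty) + c11 * ty;
  return c0 * (1 - tz) + c1 * tz;
}

// Single-beam pencil-broad-beam dose on an axis-aligned grid:
// dose(x) = fluence * exp(-mu_per_cm * WED(x)) * exp(-r^2 / (2 sigma^2))
// where WED is the water-equivalent depth integrated upstream along the
// (unit, world-axes) beam direction through the density volume, and r is the
// lateral distance from the beam axis through `iso` (mm). Density is sampled
// trilinearly; outside the grid density is 0 (air-like vacuum).
// [[Rcpp::export]]
NumericVector cpp_beam_dose(NumericVector dens, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            NumericVector dir, NumericVector iso,
                            double fluence, double mu_per_cm,
                            double sigma_mm, double step_mm) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const long n = (long)d[0] * d[1] * d[2];
  const double sp[3] = { spacing[0], spacing[1], spacing[2] };
  NumericVector out(n);
  // grid bounding box in mm (identity orientation assumed by caller)
  double lo[3], hi[3];
  for (int a = 0; a < 3; a++) {
    lo[a] = origin[a];
    hi[a] = origin[a] + sp[a] * (d[a] - 1);
  }
  long idx = 0;
  for (int k = 0; k < d[2]; k++)
    for (int j = 0; j < d[1]; j++)
      for (int i = 0; i < d[0]; i++, idx++) {
        double p[3] = { origin[0] + sp[0] * i, origin[1] + sp[1] * j,
                        origin[2] + sp[2] * k };
        // exact upstream path length to the box boundary: q(t) = p - t dir
        double tmax = R_PosInf;
        for (int a = 0; a < 3; a++) {
          if (dir[a] > 1e-12)
            tmax = std::min(tmax, (p[a] - lo[a]) / dir[a]);
          else if (dir[a] < -1e-12)
            tmax = std::min(tmax, (p[a] - hi[a]) / dir[a]);
        }
        if (!R_FINITE(tmax) || tmax < 0) tmax = 0;
        // water-equivalent depth: midpoint rule with an exact partial step
        double wed_mm = 0.0;
        int nfull = (int)std::floor(tmax / step_mm);
        for (int s = 0; s < nfull; s++) {
          double t = (s + 0.5) * step_mm;
          double rho = tri(dens.begin(), d,
                           (p[0] - t * dir[0] - origin[0]) / sp[0],
                           (p[1] - t * dir[1] - origin[1]) / sp[1],
                           (p[2] - t * dir[2] - origin[2]) / sp[2], 0.0);
          if (rho > 0) wed_mm += rho * step_mm;
        }
        double rem = tmax - nfull * step_mm;
        if (rem > 0) {
          double t = nfull * step_mm + rem / 2;
          double rho = tri(dens.begin(), d,
                           (p[0] - t * dir[0] - origin[0]) / sp[0],
                           (p[1] - t * dir[1] - origin[1]) / sp[1],
                           (p[2] - t * dir[2] - origin[2]) / sp[2], 0.0);
          if (rho > 0) wed_mm += rho * rem;
        }
        // lateral distance from beam axis through iso
        double v[3] = { p[0] - iso[0], p[1] - iso[1], p[2] - iso[2] };
        double along = v[0] * dir[0] + v[1] * dir[1] + v[2] * dir[2];
        double r2 = 0;
        for (int a = 0; a < 3; a++) {
          double lat = v[a] - along * dir[a];
          r2 += lat * lat;
        }
        out[idx] = fluence * std::exp(-mu_per_cm * wed_mm / 10.0) *
                   std::exp(-r2 / (2.0 * sigma_mm * sigma_mm));
      }
  return out;
}
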