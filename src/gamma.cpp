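#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// local trilinear sampler (NaN outside domain)
static inline double samp(const double* v, const int* d, double x, double y,
                          double z) {
  if (x < 0 || y < 0 || z < 0 || x > d[0] - 1 || y > d[1] - 1 ||
      z > d[2] - 1) return NA_REAL;
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

struct Cand { float ox, oy, oz; float d2; };

static std::vector<Cand> build_candidates(double radius, double step,
                                          const double* sp) {
  std::vector<Cand> cands;
  int nx = (int)std::floor(radius / step);
  double r2 = radius * radius;
  for (int a = -nx; a <= nx; a++)
    for (int b = -nx; b <= nx; b++)
      for (int c = -nx; c <= nx; c++) {
        double ox = a * step, oy = b * step, oz = c * step;
        double d2 = ox * ox + oy * oy + oz * oz;
        if (d2 <= r2)
          cands.push_back({ (float)ox, (float)oy, (float)oz, (float)d2 });
      }
  std::sort(cands.begin(), cands.end(),
            [](const Cand& a, const Cand& b) { return a.d2 < b.d2; });
  (void)sp;
  return cands;
}

static double gamma_at(const double* ev, const int* d, const double* sp,
                       double i, double j, double k, double dref,
                       double dta2, double denom2,
                       const std::vector<Cand>& cands) {
  double best = R_PosInf;
  for (const Cand& c : cands) {
    double dist_term = c.d2 / dta2;
    if (dist_term >= best) break;  // sorted by distance: no candidate can win
    double de = samp(ev, d, i + c.ox / sp[0], j + c.oy / sp[1],
                     k + c.oz / sp[2]);
    if (ISNAN(de)) continue;
    double dd = de - dref;
    double g2 = dist_term + dd * dd / denom2;
    if (g2 < best) best = g2;
  }
  return std::sqrt(best);
}

// 3-D gamma map. dd_frac e.g. 0.03; local: denom = dd*D_ref(x), global:
// denom = dd*dnorm_global. Coarse pass at `step`, then local refinement at
// `step`/5 in a +-step cube around the coarse optimum. Voxels below
// `floor_abs` (reference dose) or outside the mask get NA.
// [[Rcpp::export]]
NumericVector cpp_gamma(NumericVector ref, NumericVector ev,
                        IntegerVector dim, NumericVector spacing,
                        LogicalVector mask, double dd_frac, double dta,
                        bool local, double dnorm_global, double radius,
                        double step, double floor_abs, bool refine) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const long n = (long)d[0] * d[1] * d[2];
  const double sp[3] = { spacing[0], spacing[1], spacing[2] };
  NumericVector out(n, NA_REAL);
  std::vector<Cand> coarse = build_candidates(radius, step, sp);
  const double dta2 = dta * dta;
  long idx = 0;
  for (int k = 0; k < d[2]; k++)
    for (int j = 0; j < d[1]; j++)
      for (int i = 0; i < d[0]; i++, idx++) {
        if (mask.size() == n && !mask[idx]) continue;
        double dref = ref[idx];
        if (dref < floor_abs) continue;
        double dn = local ? dd_frac * dref : dd_frac * dnorm_global;
        if (dn <= 0) continue;
        double denom2 = dn * dn;
        // coarse search with early termination
        double best = R_PosInf;
        float bx = 0, by = 0, bz = 0;
        for (const Cand& c : coarse) {
          double dist_term = c.d2 / dta2;
          if (dist_term >= best) break;
          double de = samp(ev.begin(), d, i + c.ox / sp[0], j + c.oy / sp[1],
                           k + c.oz / sp[2]);
          if (ISNAN(de)) continue;
          double dd = de - dref;
          double g2 = dist_term + dd * dd / denom2;
          if (g2 < best) { best = g2; bx = c.ox; by = c.oy; bz = c.oz; }
        }
        if (!R_FINITE(best)) continue;
        if (refine) {
          double fs = step / 5.0;
          int m = 5;
          for (int a = -m; a <= m; a++)
            for (int b = -m; b <= m; b++)
              for (int c = -m; c <= m; c++) {
                double ox = bx + a * fs, oy = by + b * fs, oz = bz + c * fs;
                double d2 = ox * ox + oy * oy + oz * oz;
                double dist_term = d2 / dta2;
                if (dist_term >= best) continue;
                double de = samp(ev.begin(), d, i + ox / sp[0], j + oy / sp[1],
                                 k + oz / sp[2]);
                if (ISNAN(de)) continue;
                double dd = de - dref;
                double g2 = dist_term + dd * dd / denom2;
                if (g2 < best) best = g2;
              }
        }
        out[idx] = std::sqrt(best);
      }
  return out;
}

// Independent brute-force oracle: exhaustive distance-ordered scan of a fine
// offset lattice (caller passes the fine step, conventionally DTA/10, and
// radius 3*DTA). Shares no state with cpp_gamma beyond the inputs.
// [[Rcpp::export]]
NumericVector cpp_gamma_oracle(NumericVector ref, NumericVector ev,
                               IntegerVector dim, NumericVector spacing,
                               LogicalVector mask, double dd_frac, double dta,
                               bool local, double dnorm_global, double radius,
                               double step, double floor_abs) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const long n = (long)d[0] * d[1] * d[2];
  const double sp[3] = { spacing[0], spacing[1], spacing[2] };
  NumericVector out(n, NA_REAL);
  std::vector<Cand> cands = build_candidates(radius, step, sp);
  const double dta2 = dta * dta;
  long idx = 0;
  for (int k = 0; k < d[2]; k++)
    for (int j = 0; j < d[1]; j++)
      for (int i = 0; i < d[0]; i++, idx++) {
        if (mask.size() == n && !mask[idx]) continue;
        double dref = ref[idx];
        if (dref < floor_abs) continue;
        double dn = local ? dd_frac * dref : dd_frac * dnorm_global;
        if (dn <= 0) continue;
        double g = gamma_at(ev.begin(), d, sp, i, j, k, dref, dta2, dn * dn,
                            cands);
        if (R_FINITE(g)) out[idx] = g;
      }
  return out;
}
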