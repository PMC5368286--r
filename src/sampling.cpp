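#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear / nearest sampling of a 3-D lattice at continuous 0-based voxel
// coordinates. Out-of-domain points receive `fill`.
static inline double sample_tri(const double* v, const int* d,
                                double x, double y, double z, double fill) {
  if (x < 0 || y < 0 || z < 0 ||
      x > d[0] - 1 || y > d[1] - 1 || z > d[2] - 1) return fill;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == d[0] - 1) i0--;
  if (j0 == d[1] - 1) j0--;
  if (k0 == d[2] - 1) k0--;
  if (d[0] == 1) i0 = 0;
  if (d[1] == 1) j0 = 0;
  if (d[2] == 1) k0 = 0;
  double tx = x - i0, ty = y - j0, tz = z - k0;
  const long nx = d[0], nxy = (long)d[0] * d[1];
  const double* p = v + i0 + nx * j0 + nxy * k0;
  int si = (d[0] > 1) ? 1 : 0;
  long sj = (d[1] > 1) ? nx : 0, sk = (d[2] > 1) ? nxy : 0;
  double c00 = p[0] * (1 - tx) + p[si] * tx;
  double c10 = p[sj] * (1 - tx) + p[sj + si] * tx;
  double c01 = p[sk] * (1 - tx) + p[sk + si] * tx;
  double c11 = p[sj + sk] * (1 - tx) + p[sj + sk + si] * tx;
  double c0 = c00 * (1 - ty) + c10 * ty;
  double c1 = c01 * (1 - ty) + c11 * ty;
  return c0 * (1 - tz) + c1 * tz;
}

static inline double sample_nn(const double* v, const int* d,
                               double x, double y, double z, double fill) {
  long i = (long)std::floor(x + 0.5), j = (long)std::floor(y + 0.5),
       k = (long)std::floor(z + 0.5);
  if (i < 0 || j < 0 || k < 0 || i >= d[0] || j >= d[1] || k >= d[2])
    return fill;
  return v[i + (long)d[0] * j + (long)d[0] * d[1] * k];
}

// Pull-back resampling with optional world-space affine map and/or dense
// displacement field (mm, on the target grid, world axes).
//
// For target voxel index i: w = or_t + R_t (sp_t * i); if affine given,
// w <- M w + t; if field given, w <- w + u(i); then map w into the input
// lattice and interpolate.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector values, IntegerVector dim_in,
                           NumericVector sp_in, NumericVector or_in,
                           NumericVector R_in, IntegerVector dim_t,
                           NumericVector sp_t, NumericVector or_t,
                           NumericVector R_t, Nullable<NumericVector> affine,
                           Nullable<NumericVector> field, int interp,
                           double fill) {
  const int dI[3] = { dim_in[0], dim_in[1], dim_in[2] };
  const int dT[3] = { dim_t[0], dim_t[1], dim_t[2] };
  const long nT = (long)dT[0] * dT[1] * dT[2];
  NumericVector out(nT);
  const double* v = values.begin();
  const double* Ri = R_in.begin();  // column-major 3x3
  const double* Rt = R_t.begin();
  bool has_aff = affine.isNotNull(), has_field = field.isNotNull();
  double M[9], tv[3];
  if (has_aff) {
    NumericVector a(affine);  // 12 numbers: 3x3 col-major + translation
    for (int q = 0; q < 9; q++) M[q] = a[q];
    for (int q = 0; q < 3; q++) tv[q] = a[9 + q];
  }
  const double* U = has_field ? NumericVector(field).begin() : nullptr;
  long idx = 0;
  for (int k = 0; k < dT[2]; k++)
    for (int j = 0; j < dT[1]; j++)
      for (int i = 0; i < dT[0]; i++, idx++) {
        double li = sp_t[0] * i, lj = sp_t[1] * j, lk = sp_t[2] * k;
        double wx = or_t[0] + Rt[0] * li + Rt[3] * lj + Rt[6] * lk;
        double wy = or_t[1] + Rt[1] * li + Rt[4] * lj + Rt[7] * lk;
        double wz = or_t[2] + Rt[2] * li + Rt[5] * lj + Rt[8] * lk;
        if (has_aff) {
          double ax = M[0] * wx + M[3] * wy + M[6] * wz + tv[0];
          double ay = M[1] * wx + M[4] * wy + M[7] * wz + tv[1];
          double az = M[2] * wx + M[5] * wy + M[8] * wz + tv[2];
          wx = ax; wy = ay; wz = az;
        }
        if (has_field) {
          wx += U[idx]; wy += U[idx + nT]; wz += U[idx + 2 * nT];
        }
        // world -> input voxel: ci = (R_in^T (w - origin)) / spacing
        double qx = wx - or_in[0], qy = wy - or_in[1], qz = wz - or_in[2];
        double cx = (Ri[0] * qx + Ri[1] * qy + Ri[2] * qz) / sp_in[0];
        double cy = (Ri[3] * qx + Ri[4] * qy + Ri[5] * qz) / sp_in[1];
        double cz = (Ri[6] * qx + Ri[7] * qy + Ri[8] * qz) / sp_in[2];
        out[idx] = (interp == 0) ? sample_nn(v, dI, cx, cy, cz, fill)
                                 : sample_tri(v, dI, cx, cy, cz, fill);
      }
  return out;
}

// Clamped trilinear interpolation of a 3-D array at continuous 0-based
// voxel coordinates (N x 3 matrix).
// [[Rcpp::export]]
NumericVector cpp_interp_points(NumericVector values, IntegerVector dim,
                                NumericMatrix pts) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const int N = pts.nrow();
  NumericVector out(N);
  for (int s = 0; s < N; s++) {
    double x = pts(s, 0), y = pts(s, 1), z = pts(s, 2);
    if (x < 0) x = 0; if (x > d[0] - 1) x = d[0] - 1;
    if (y < 0) y = 0; if (y > d[1] - 1) y = d[1] - 1;
    if (z < 0) z = 0; if (z > d[2] - 1) z = d[2] - 1;
    out[s] = sample_tri(values.begin(), d, x, y, z, 0.0);
  }
  return out;
}

// Fixed-point inversion of a displacement field (same-grid, axis-aligned
// identity-orientation assumption is NOT required: displacements are in mm
// world axes, and lookups convert via R^T / spacing of the field grid).
// v_{n+1}(x) = -u(x + v_n(x))
// [[Rcpp::export]]
NumericVector cpp_invert_field(NumericVector U, IntegerVector dim,
                               NumericVector sp, NumericVector Rmat,
                               int max_iter, double tol_mm) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const long n = (long)d[0] * d[1] * d[2];
  NumericVector V(3 * n);  // starts at zero
  const double* u = U.begin();
  const double* R = Rmat.begin();
  std::vector<double> Vn(3 * n);
  for (int it = 0; it < max_iter; it++) {
    double max_delta = 0.0;
    long idx = 0;
    for (int k = 0; k < d[2]; k++)
      for (int j = 0; j < d[1]; j++)
        for (int i = 0; i < d[0]; i++, idx++) {
          double vx = V[idx], vy = V[idx + n], vz = V[idx + 2 * n];
          // voxel offset of v in field-grid index coords
          double cx = i + (R[0] * vx + R[1] * vy + R[2] * vz) / sp[0];
          double cy = j + (R[3] * vx + R[4] * vy + R[5] * vz) / sp[1];
          double cz = k + (R[6] * vx + R[7] * vy + R[8] * vz) / sp[2];
          // clamp to domain (field extended by nearest edge value)
          if (cx < 0) cx = 0; if (cx > d[0] - 1) cx = d[0] - 1;
          if (cy < 0) cy = 0; if (cy > d[1] - 1) cy = d[1] - 1;
          if (cz < 0) cz = 0; if (cz > d[2] - 1) cz = d[2] - 1;
          double nx = -sample_tri(u, d, cx, cy, cz, 0.0);
          double ny = -sample_tri(u + n, d, cx, cy, cz, 0.0);
          double nz = -sample_tri(u + 2 * n, d, cx, cy, cz, 0.0);
          double dd = std::sqrt((nx - vx) * (nx - vx) + (ny - vy) * (ny - vy) +
                                (nz - vz) * (nz - vz));
          if (dd > max_delta) max_delta = dd;
          Vn[idx] = nx; Vn[idx + n] = ny; Vn[idx + 2 * n] = nz;
        }
    std::copy(Vn.begin(), Vn.end(), V.begin());
    if (max_delta < tol_mm) break;
  }
  return V;
}
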