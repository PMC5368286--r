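#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- shared helpers ------------------------------------------------------

static inline double tri3(const double* v, const int* d, double x, double y,
                          double z, bool& in) {
  if (x < 0 || y < 0 || z < 0 || x > d[0] - 1 || y > d[1] - 1 ||
      z > d[2] - 1) { in = false; return 0.0; }
  in = true;
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

// scale intensity to bin coordinate in [0, bins-1], returning floor bin and
// fractional part for linear (partial-volume) spreading
static inline void bin_coord(double v, double lo, double hi, int bins,
                             int& b0, double& t) {
  double s = (hi > lo) ? (v - lo) / (hi - lo) * (bins - 1) : 0.0;
  if (s < 0) s = 0;
  if (s > bins - 1) s = bins - 1;
  b0 = (int)std::floor(s);
  if (b0 >= bins - 1) b0 = bins - 2;
  t = s - b0;
}

struct NmiParts { double Hf, Hm, Hfm, nmi; };

// entropies from a joint histogram (bins x bins, counts), N = total
static NmiParts nmi_from_hist(const std::vector<double>& H, int bins,
                              double N) {
  std::vector<double> pf(bins, 0.0), pm(bins, 0.0);
  double Hfm = 0;
  for (int a = 0; a < bins; a++)
    for (int b = 0; b < bins; b++) {
      double p = H[a + bins * b] / N;
      if (p > 0) {
        Hfm -= p * std::log(p);
        pf[a] += p;
        pm[b] += p;
      }
    }
  double Hf = 0, Hm = 0;
  for (int a = 0; a < bins; a++) {
    if (pf[a] > 0) Hf -= pf[a] * std::log(pf[a]);
    if (pm[a] > 0) Hm -= pm[a] * std::log(pm[a]);
  }
  NmiParts r;
  r.Hf = Hf; r.Hm = Hm; r.Hfm = Hfm;
  r.nmi = (Hfm > 0) ? (Hf + Hm) / Hfm : 1.0;
  return r;
}

// ---- plain NMI of two same-grid vectors over an include mask -------------
// [[Rcpp::export]]
double cpp_nmi_vec(NumericVector f, NumericVector m, LogicalVector inc,
                   int bins) {
  double flo = R_PosInf, fhi = R_NegInf, mlo = R_PosInf, mhi = R_NegInf;
  const long n = f.size();
  for (long i = 0; i < n; i++) {
    if (!inc[i]) continue;
    if (f[i] < flo) flo = f[i];
    if (f[i] > fhi) fhi = f[i];
    if (m[i] < mlo) mlo = m[i];
    if (m[i] > mhi) mhi = m[i];
  }
  std::vector<double> H(bins * bins, 0.0);
  double N = 0;
  for (long i = 0; i < n; i++) {
    if (!inc[i]) continue;
    int a0, b0; double ta, tb;
    bin_coord(f[i], flo, fhi, bins, a0, ta);
    bin_coord(m[i], mlo, mhi, bins, b0, tb);
    H[a0 + bins * b0] += (1 - ta) * (1 - tb);
    H[a0 + 1 + bins * b0] += ta * (1 - tb);
    H[a0 + bins * (b0 + 1)] += (1 - ta) * tb;
    H[a0 + 1 + bins * (b0 + 1)] += ta * tb;
    N += 1;
  }
  if (N < 8) return NA_REAL;
  return nmi_from_hist(H, bins, N).nmi;
}

// ---- NMI under a world-space affine map (for affine registration) --------
// Moving volume sampled at M w + t for each (strided) fixed voxel; voxels
// mapping outside the moving domain are excluded.
// [[Rcpp::export]]
double cpp_nmi_affine(NumericVector fvals, IntegerVector fdim,
                      NumericVector fsp, NumericVector forg, NumericVector fR,
                      NumericVector mvals, IntegerVector mdim,
                      NumericVector msp, NumericVector morg, NumericVector mR,
                      NumericVector aff, int bins, int stride,
                      Nullable<LogicalVector> fmask) {
  const int dF[3] = { fdim[0], fdim[1], fdim[2] };
  const int dM[3] = { mdim[0], mdim[1], mdim[2] };
  const double* Rf = fR.begin();
  const double* Rm = mR.begin();
  double M[9], tv[3];
  for (int q = 0; q < 9; q++) M[q] = aff[q];
  for (int q = 0; q < 3; q++) tv[q] = aff[9 + q];
  bool has_mask = fmask.isNotNull();
  LogicalVector msk = has_mask ? LogicalVector(fmask) : LogicalVector(0);

  std::vector<double> fs, ms;
  fs.reserve(fvals.size() / (stride * stride * stride) + 16);
  for (int k = 0; k < dF[2]; k += stride)
    for (int j = 0; j < dF[1]; j += stride)
      for (int i = 0; i < dF[0]; i += stride) {
        long idx = i + (long)dF[0] * j + (long)dF[0] * dF[1] * k;
        if (has_mask && !msk[idx]) continue;
        double li = fsp[0] * i, lj = fsp[1] * j, lk = fsp[2] * k;
        double wx = forg[0] + Rf[0] * li + Rf[3] * lj + Rf[6] * lk;
        double wy = forg[1] + Rf[1] * li + Rf[4] * lj + Rf[7] * lk;
        double wz = forg[2] + Rf[2] * li + Rf[5] * lj + Rf[8] * lk;
        double ax = M[0] * wx + M[3] * wy + M[6] * wz + tv[0];
        double ay = M[1] * wx + M[4] * wy + M[7] * wz + tv[1];
        double az = M[2] * wx + M[5] * wy + M[8] * wz + tv[2];
        double qx = ax - morg[0], qy = ay - morg[1], qz = az - morg[2];
        double cx = (Rm[0] * qx + Rm[1] * qy + Rm[2] * qz) / msp[0];
        double cy = (Rm[3] * qx + Rm[4] * qy + Rm[5] * qz) / msp[1];
        double cz = (Rm[6] * qx + Rm[7] * qy + Rm[8] * qz) / msp[2];
        bool in;
        double mv = tri3(mvals.begin(), dM, cx, cy, cz, in);
        if (!in) continue;
        fs.push_back(fvals[idx]);
        ms.push_back(mv);
      }
  long N = fs.size();
  if (N < 64) return NA_REAL;
  double flo = fs[0], fhi = fs[0], mlo = ms[0], mhi = ms[0];
  for (long i = 0; i < N; i++) {
    if (fs[i] < flo) flo = fs[i];
    if (fs[i] > fhi) fhi = fs[i];
    if (ms[i] < mlo) mlo = ms[i];
    if (ms[i] > mhi) mhi = ms[i];
  }
  std::vector<double> H(bins * bins, 0.0);
  for (long i = 0; i < N; i++) {
    int a0, b0; double ta, tb;
    bin_coord(fs[i], flo, fhi, bins, a0, ta);
    bin_coord(ms[i], mlo, mhi, bins, b0, tb);
    H[a0 + bins * b0] += (1 - ta) * (1 - tb);
    H[a0 + 1 + bins * b0] += ta * (1 - tb);
    H[a0 + bins * (b0 + 1)] += (1 - ta) * tb;
    H[a0 + 1 + bins * (b0 + 1)] += ta * tb;
  }
  return nmi_from_hist(H, bins, (double)N).nmi;
}

// ---- cubic B-spline FFD --------------------------------------------------

static inline void bspline_w(double t, double* w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
  w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// Per-axis lookup tables: base control index and 4 weights per voxel index.
struct AxisLut {
  std::vector<int> base;
  std::vector<double> w;  // 4 per voxel
};

static AxisLut make_lut(int len, double delta) {
  AxisLut L;
  L.base.resize(len);
  L.w.resize(4 * len);
  for (int i = 0; i < len; i++) {
    double s = i / delta;
    int ib = (int)std::floor(s);
    double t = s - ib;
    L.base[i] = ib;  // control points used: ib .. ib+3 (grid offset -1 built in)
    bspline_w(t, &L.w[4 * i]);
  }
  return L;
}

// Dense displacement (voxel units, 3*n) from control coefficients
// C dims (nc1, nc2, nc3, 3).
// [[Rcpp::export]]
NumericVector cpp_ffd_field(NumericVector C, IntegerVector dim,
                            NumericVector delta, IntegerVector nc) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const long n = (long)d[0] * d[1] * d[2];
  const long ncl = (long)nc[0] * nc[1] * nc[2];
  AxisLut Lx = make_lut(d[0], delta[0]), Ly = make_lut(d[1], delta[1]),
          Lz = make_lut(d[2], delta[2]);
  NumericVector U(3 * n);
  long idx = 0;
  for (int k = 0; k < d[2]; k++)
    for (int j = 0; j < d[1]; j++)
      for (int i = 0; i < d[0]; i++, idx++) {
        double u[3] = { 0, 0, 0 };
        for (int c2 = 0; c2 < 4; c2++) {
          double wz = Lz.w[4 * k + c2];
          long kz = (long)(Lz.base[k] + c2) * nc[0] * nc[1];
          for (int c1 = 0; c1 < 4; c1++) {
            double wyz = Ly.w[4 * j + c1] * wz;
            long kyz = kz + (long)(Ly.base[j] + c1) * nc[0];
            for (int c0 = 0; c0 < 4; c0++) {
              double w = Lx.w[4 * i + c0] * wyz;
              long ci = kyz + Lx.base[i] + c0;
              u[0] += w * C[ci];
              u[1] += w * C[ci + ncl];
              u[2] += w * C[ci + 2 * ncl];
            }
          }
        }
        U[idx] = u[0]; U[idx + n] = u[1]; U[idx + 2 * n] = u[2];
      }
  return U;
}

// Multi-channel NMI + bending-energy objective and analytic gradient for a
// cubic B-spline FFD. Fixed and moving channels share one grid (moving
// already carries the affine initialization); displacements are in voxel
// units of that grid. Returns list(value, grad); value is the quantity to
// MAXIMIZE: sum_c w_c NMI_c - bend_w * E_bend.
// [[Rcpp::export]]
List cpp_ffd_obj(NumericVector C, List fixed, List moving, List mgrad,
                 IntegerVector dim, NumericVector delta, IntegerVector nc,
                 int bins, NumericVector cw, double bend_w,
                 LogicalVector mask, bool want_grad) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const long n = (long)d[0] * d[1] * d[2];
  const long ncl = (long)nc[0] * nc[1] * nc[2];
  const int nch = fixed.size();
  AxisLut Lx = make_lut(d[0], delta[0]), Ly = make_lut(d[1], delta[1]),
          Lz = make_lut(d[2], delta[2]);

  // geometry pass: displaced coordinates + inclusion
  std::vector<long> vox;
  std::vector<float> cx, cy, cz;
  vox.reserve(n / 2);
  {
    long idx = 0;
    for (int k = 0; k < d[2]; k++)
      for (int j = 0; j < d[1]; j++)
        for (int i = 0; i < d[0]; i++, idx++) {
          if (mask.size() == n && !mask[idx]) continue;
          double u[3] = { 0, 0, 0 };
          for (int c2 = 0; c2 < 4; c2++) {
            double wz = Lz.w[4 * k + c2];
            long kz = (long)(Lz.base[k] + c2) * nc[0] * nc[1];
            for (int c1 = 0; c1 < 4; c1++) {
              double wyz = Ly.w[4 * j + c1] * wz;
              long kyz = kz + (long)(Ly.base[j] + c1) * nc[0];
              for (int c0 = 0; c0 < 4; c0++) {
                double w = Lx.w[4 * i + c0] * wyz;
                long ci = kyz + Lx.base[i] + c0;
                u[0] += w * C[ci];
                u[1] += w * C[ci + ncl];
                u[2] += w * C[ci + 2 * ncl];
              }
            }
          }
          double px = i + u[0], py = j + u[1], pz = k + u[2];
          if (px < 0 || py < 0 || pz < 0 || px > d[0] - 1 || py > d[1] - 1 ||
              pz > d[2] - 1)
            continue;
          vox.push_back(idx);
          cx.push_back((float)px);
          cy.push_back((float)py);
          cz.push_back((float)pz);
        }
  }
  const long N = vox.size();
  NumericVector grad(want_grad ? 3 * ncl : 1);
  if (N < 64) {
    // keep the objective finite so line searches can back off
    return List::create(_["value"] = -1e6, _["grad"] = grad,
                        _["n"] = (double)N);
  }

  // per-channel: sample moving, histogram, NMI, and (optionally) the voxel
  // chain term dNMI/dm' for the gradient pass
  double value = 0.0;
  std::vector<std::vector<float>> msamp(nch);
  std::vector<double> flo(nch), fhi(nch), mlo(nch), mhi(nch);
  std::vector<std::vector<double>> logP(nch), logpm(nch);
  std::vector<NmiParts> parts(nch);
  for (int c = 0; c < nch; c++) {
    NumericVector f = fixed[c], m = moving[c];
    const double* mp = m.begin();
    msamp[c].resize(N);
    double a = R_PosInf, b = R_NegInf, p = R_PosInf, q = R_NegInf;
    for (long s = 0; s < N; s++) {
      bool in;
      double mv = tri3(mp, d, cx[s], cy[s], cz[s], in);
      msamp[c][s] = (float)mv;
      double fv = f[vox[s]];
      if (fv < a) a = fv;
      if (fv > b) b = fv;
      if (mv < p) p = mv;
      if (mv > q) q = mv;
    }
    flo[c] = a; fhi[c] = b; mlo[c] = p; mhi[c] = q;
    std::vector<double> H(bins * bins, 0.0);
    for (long s = 0; s < N; s++) {
      int a0, b0; double ta, tb;
      bin_coord(f[vox[s]], a, b, bins, a0, ta);
      bin_coord(msamp[c][s], p, q, bins, b0, tb);
      H[a0 + bins * b0] += (1 - ta) * (1 - tb);
      H[a0 + 1 + bins * b0] += ta * (1 - tb);
      H[a0 + bins * (b0 + 1)] += (1 - ta) * tb;
      H[a0 + 1 + bins * (b0 + 1)] += ta * tb;
    }
    parts[c] = nmi_from_hist(H, bins, (double)N);
    value += cw[c] * parts[c].nmi;
    if (want_grad) {
      logP[c].assign(bins * bins, 0.0);
      logpm[c].assign(bins, 0.0);
      std::vector<double> pm(bins, 0.0);
      for (int bb = 0; bb < bins; bb++)
        for (int aa = 0; aa < bins; aa++) pm[bb] += H[aa + bins * bb];
      const double tiny = 1e-12;
      for (int t = 0; t < bins * bins; t++)
        logP[c][t] = std::log(std::max(H[t] / (double)N, tiny));
      for (int bb = 0; bb < bins; bb++)
        logpm[c][bb] = std::log(std::max(pm[bb] / (double)N, tiny));
    }
  }

  // bending energy on the control lattice (axial second differences)
  double Ebend = 0.0;
  std::vector<double> bgrad;
  if (bend_w > 0) bgrad.assign(3 * ncl, 0.0);
  if (bend_w > 0) {
    const long cst[3] = { 1, nc[0], (long)nc[0] * nc[1] };
    for (int ax = 0; ax < 3; ax++) {
      for (int k = 0; k < nc[2]; k++)
        for (int j = 0; j < nc[1]; j++)
          for (int i = 0; i < nc[0]; i++) {
            int pos[3] = { i, j, k };
            if (pos[ax] < 1 || pos[ax] > ((int)((ax == 0) ? nc[0] : (ax == 1) ? nc[1] : nc[2])) - 2)
              continue;
            long cidx = i + (long)nc[0] * j + (long)nc[0] * nc[1] * k;
            for (int comp = 0; comp < 3; comp++) {
              long o = comp * ncl;
              double sd = C[cidx - cst[ax] + o] - 2 * C[cidx + o] +
                          C[cidx + cst[ax] + o];
              Ebend += sd * sd;
              bgrad[cidx - cst[ax] + o] += 2 * sd;
              bgrad[cidx + o] += -4 * sd;
              bgrad[cidx + cst[ax] + o] += 2 * sd;
            }
          }
    }
  }
  value -= bend_w * Ebend;

  if (!want_grad) {
    return List::create(_["value"] = value, _["grad"] = grad,
                        _["n"] = (double)N);
  }

  // gradient pass
  std::vector<double> G(3 * ncl, 0.0);
  for (long s = 0; s < N; s++) {
    long idx = vox[s];
    long i = idx % d[0], j = (idx / d[0]) % d[1], k = idx / ((long)d[0] * d[1]);
    double gvox[3] = { 0, 0, 0 };
    for (int c = 0; c < nch; c++) {
      if (cw[c] == 0) continue;
      NumericVector f = fixed[c];
      int a0, b0; double ta, tb;
      bin_coord(f[idx], flo[c], fhi[c], bins, a0, ta);
      bin_coord(msamp[c][s], mlo[c], mhi[c], bins, b0, tb);
      // d Hfm / dm' and d Hm / dm' (per-voxel, already /N)
      double dHfm = -((1 - ta) * (logP[c][a0 + bins * (b0 + 1)] -
                                  logP[c][a0 + bins * b0]) +
                      ta * (logP[c][a0 + 1 + bins * (b0 + 1)] -
                            logP[c][a0 + 1 + bins * b0])) / (double)N;
      double dHm = -(logpm[c][b0 + 1] - logpm[c][b0]) / (double)N;
      const NmiParts& P = parts[c];
      double dnmi = (dHm * P.Hfm - (P.Hf + P.Hm) * dHfm) / (P.Hfm * P.Hfm);
      // m' is in bin units: chain through intensity scale
      double mscale = (mhi[c] > mlo[c]) ? (bins - 1) / (mhi[c] - mlo[c]) : 0.0;
      // spatial gradient of moving channel (intensity per voxel index)
      NumericVector g = mgrad[c];
      const double* gp = g.begin();
      bool in;
      double gx = tri3(gp, d, cx[s], cy[s], cz[s], in);
      double gy = tri3(gp + n, d, cx[s], cy[s], cz[s], in);
      double gz = tri3(gp + 2 * n, d, cx[s], cy[s], cz[s], in);
      double coef = cw[c] * dnmi * mscale;
      gvox[0] += coef * gx;
      gvox[1] += coef * gy;
      gvox[2] += coef * gz;
    }
    // scatter into control-point gradient
    for (int c2 = 0; c2 < 4; c2++) {
      double wz = Lz.w[4 * k + c2];
      long kz = (long)(Lz.base[k] + c2) * nc[0] * nc[1];
      for (int c1 = 0; c1 < 4; c1++) {
        double wyz = Ly.w[4 * j + c1] * wz;
        long kyz = kz + (long)(Ly.base[j] + c1) * nc[0];
        for (int c0 = 0; c0 < 4; c0++) {
          double w = Lx.w[4 * i + c0] * wyz;
          long ci = kyz + Lx.base[i] + c0;
          G[ci] += w * gvox[0];
          G[ci + ncl] += w * gvox[1];
          G[ci + 2 * ncl] += w * gvox[2];
        }
      }
    }
  }
  if (bend_w > 0)
    for (long t = 0; t < 3 * ncl; t++) G[t] -= bend_w * bgrad[t];
  std::copy(G.begin(), G.end(), grad.begin());
  return List::create(_["value"] = value, _["grad"] = grad,
                      _["n"] = (double)N);
}

// central-difference spatial gradient (intensity per voxel index), 3*n
// [[Rcpp::export]]
NumericVector cpp_grad3d(NumericVector x, IntegerVector dim) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const long n = (long)d[0] * d[1] * d[2];
  const long stride[3] = { 1, (long)d[0], (long)d[0] * d[1] };
  NumericVector g(3 * n);
  long idx = 0;
  for (int k = 0; k < d[2]; k++)
    for (int j = 0; j < d[1]; j++)
      for (int i = 0; i < d[0]; i++, idx++) {
        int pos[3] = { i, j, k };
        for (int ax = 0; ax < 3; ax++) {
          long hi = idx, lo = idx;
          double den = 0;
          if (pos[ax] + 1 < d[ax]) { hi = idx + stride[ax]; den += 1; }
          if (pos[ax] - 1 >= 0) { lo = idx - stride[ax]; den += 1; }
          g[idx + ax * n] = (den > 0) ? (x[hi] - x[lo]) / den : 0.0;
        }
      }
  return g;
}
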