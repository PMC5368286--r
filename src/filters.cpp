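#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Separable Gaussian smoothing, reflected boundaries, sigma in voxels/axis.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector x, IntegerVector dim,
                          NumericVector sigma) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const long n = (long)d[0] * d[1] * d[2];
  std::vector<double> a(x.begin(), x.end()), b(n);
  const long stride[3] = { 1, (long)d[0], (long)d[0] * d[1] };
  for (int ax = 0; ax < 3; ax++) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * r + 1);
    double sum = 0;
    for (int q = -r; q <= r; q++) {
      k[q + r] = std::exp(-0.5 * q * q / (s * s));
      sum += k[q + r];
    }
    for (auto& w : k) w /= sum;
    int len = d[ax];
    long st = stride[ax];
    // iterate over all lines along axis ax
    long nlines = n / len;
    for (long line = 0; line < nlines; line++) {
      // compute base index of this line
      long rem = line, base = 0;
      for (int o = 0; o < 3; o++) {
        if (o == ax) continue;
        long sz = d[o];
        base += (rem % sz) * stride[o];
        rem /= sz;
      }
      for (int p = 0; p < len; p++) {
        double acc = 0;
        for (int q = -r; q <= r; q++) {
          int pp = p + q;
          if (pp < 0) pp = -pp - 1;            // reflect
          if (pp >= len) pp = 2 * len - pp - 1;
          if (pp < 0) pp = 0;
          if (pp >= len) pp = len - 1;
          acc += k[q + r] * a[base + (long)pp * st];
        }
        b[base + (long)p * st] = acc;
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// Binary erosion/dilation with an explicit structuring-element offset list
// (K x 3 integer matrix of voxel offsets). mode: 0 = dilate, 1 = erode.
// [[Rcpp::export]]
LogicalVector cpp_morph(LogicalVector mask, IntegerVector dim,
                        IntegerMatrix offsets, int mode) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const long n = (long)d[0] * d[1] * d[2];
  LogicalVector out(n);
  const int K = offsets.nrow();
  long idx = 0;
  for (int k = 0; k < d[2]; k++)
    for (int j = 0; j < d[1]; j++)
      for (int i = 0; i < d[0]; i++, idx++) {
        bool hit = (mode == 1);  // erode: all must be set; dilate: any
        for (int q = 0; q < K; q++) {
          int ii = i + offsets(q, 0), jj = j + offsets(q, 1),
              kk = k + offsets(q, 2);
          bool val;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] ||
              kk >= d[2])
            // outside the grid: background for dilation, foreground for
            // erosion, so closing stays extensive and opening anti-extensive
            // at the grid border
            val = (mode == 1);
          else
            val = mask[ii + (long)d[0] * jj + (long)d[0] * d[1] * kk];
          if (mode == 0) { if (val) { hit = true; break; } }
          else           { if (!val) { hit = false; break; } }
        }
        out[idx] = hit;
      }
  return out;
}

// 6-connected component labelling; returns integer labels (0 = background),
// components numbered in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dim) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const long n = (long)d[0] * d[1] * d[2];
  IntegerVector lab(n);  // zeros
  const long stride[3] = { 1, (long)d[0], (long)d[0] * d[1] };
  int next = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    next++;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      long c = stack.back();
      stack.pop_back();
      long ci = c % d[0], cj = (c / d[0]) % d[1], ck = c / (d[0] * (long)d[1]);
      const long coords[3] = { ci, cj, ck };
      for (int ax = 0; ax < 3; ax++)
        for (int dir = -1; dir <= 1; dir += 2) {
          long p = coords[ax] + dir;
          if (p < 0 || p >= d[ax]) continue;
          long t = c + dir * stride[ax];
          if (mask[t] && !lab[t]) { lab[t] = next; stack.push_back(t); }
        }
    }
  }
  return lab;
}

// Background reachable from the border by 6-connectivity (for hole filling:
// holes = !mask & !reachable).
// [[Rcpp::export]]
LogicalVector cpp_border_background(LogicalVector mask, IntegerVector dim) {
  const int d[3] = { dim[0], dim[1], dim[2] };
  const long n = (long)d[0] * d[1] * d[2];
  LogicalVector reach(n);
  const long stride[3] = { 1, (long)d[0], (long)d[0] * d[1] };
  std::vector<long> stack;
  long idx = 0;
  for (int k = 0; k < d[2]; k++)
    for (int j = 0; j < d[1]; j++)
      for (int i = 0; i < d[0]; i++, idx++) {
        bool border = (i == 0 || j == 0 || k == 0 || i == d[0] - 1 ||
                       j == d[1] - 1 || k == d[2] - 1);
        if (border && !mask[idx] && !reach[idx]) {
          reach[idx] = true;
          stack.push_back(idx);
        }
      }
  while (!stack.empty()) {
    long c = stack.back();
    stack.pop_back();
    long ci = c % d[0], cj = (c / d[0]) % d[1], ck = c / (d[0] * (long)d[1]);
    const long coords[3] = { ci, cj, ck };
    for (int ax = 0; ax < 3; ax++)
      for (int dir = -1; dir <= 1; dir += 2) {
        long p = coords[ax] + dir;
        if (p < 0 || p >= d[ax]) continue;
        long t = c + dir * stride[ax];
        if (!mask[t] && !reach[t]) { reach[t] = true; stack.push_back(t); }
      }
  }
  return reach;
}
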