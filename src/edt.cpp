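#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact anisotropic squared Euclidean distance transform (separable
// lower-envelope-of-parabolas algorithm), per-axis sample spacing w.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double w) {
  const double BIG = 1e30;
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * w;
    double s;
    while (true) {
      int p = v[k];
      double xp = p * w;
      s = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2.0 * (xq - xp));
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * w;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Squared distance (in physical units) from every voxel center to the
// nearest voxel center of the mask support. Empty mask -> all >= 1e30.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dims");
  const double BIG = 1e30;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (fastest)
  for (int c = 0; c < d3; ++c)
    for (int b = 0; b < d2; ++b) {
      R_xlen_t base = (R_xlen_t)d1 * (b + (R_xlen_t)d2 * c);
      bool any = false;
      for (int a = 0; a < d1; ++a) { f[a] = out[base + a]; if (f[a] < BIG) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, d1, spacing[0]);
      for (int a = 0; a < d1; ++a) out[base + a] = d[a];
    }
  // axis 2
  for (int c = 0; c < d3; ++c)
    for (int a = 0; a < d1; ++a) {
      bool any = false;
      for (int b = 0; b < d2; ++b) {
        f[b] = out[a + (R_xlen_t)d1 * (b + (R_xlen_t)d2 * c)];
        if (f[b] < BIG) any = true;
      }
      if (!any) continue;
      dt1d(f, d, v, z, d2, spacing[1]);
      for (int b = 0; b < d2; ++b) out[a + (R_xlen_t)d1 * (b + (R_xlen_t)d2 * c)] = d[b];
    }
  // axis 3
  for (int b = 0; b < d2; ++b)
    for (int a = 0; a < d1; ++a) {
      bool any = false;
      for (int c = 0; c < d3; ++c) {
        f[c] = out[a + (R_xlen_t)d1 * (b + (R_xlen_t)d2 * c)];
        if (f[c] < BIG) any = true;
      }
      if (!any) continue;
      dt1d(f, d, v, z, d3, spacing[2]);
      for (int c = 0; c < d3; ++c) out[a + (R_xlen_t)d1 * (b + (R_xlen_t)d2 * c)] = d[c];
    }
  return out;
}
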