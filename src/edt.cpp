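#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher, squared
// form), separable lower-envelope scan per axis. Distances are voxel
// centre-to-centre; feature voxels get 0.

static const double DT_INF = std::numeric_limits<double>::infinity();

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == DT_INF) continue; // infinite parabolas never enter the envelope
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k >= 0 && s <= z[k]) {
      --k;
      if (k >= 0)
        s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
            (2.0 * q - 2.0 * v[k]);
    }
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -DT_INF;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
    }
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3_cpp")]]
NumericVector edt3_cpp(LogicalVector feature, IntegerVector dims) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  const R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (feature[i] == TRUE) ? 0.0 : DT_INF;

  int nmax = std::max(d0, std::max(d1, d2));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 0 (fastest-varying index)
  for (int i2 = 0; i2 < d2; ++i2)
    for (int i1 = 0; i1 < d1; ++i1) {
      R_xlen_t base = (R_xlen_t)d0 * (i1 + (R_xlen_t)d1 * i2);
      bool any = false;
      for (int i0 = 0; i0 < d0; ++i0) {
        f[i0] = out[base + i0];
        if (f[i0] < DT_INF) any = true;
      }
      if (!any) continue;
      dt1d(f, d, v, z, d0);
      for (int i0 = 0; i0 < d0; ++i0) out[base + i0] = d[i0];
    }
  // axis 1
  for (int i2 = 0; i2 < d2; ++i2)
    for (int i0 = 0; i0 < d0; ++i0) {
      R_xlen_t base = i0 + (R_xlen_t)d0 * d1 * i2;
      bool any = false;
      for (int i1 = 0; i1 < d1; ++i1) {
        f[i1] = out[base + (R_xlen_t)d0 * i1];
        if (f[i1] < DT_INF) any = true;
      }
      if (!any) continue;
      dt1d(f, d, v, z, d1);
      for (int i1 = 0; i1 < d1; ++i1) out[base + (R_xlen_t)d0 * i1] = d[i1];
    }
  // axis 2
  const R_xlen_t s2 = (R_xlen_t)d0 * d1;
  for (int i1 = 0; i1 < d1; ++i1)
    for (int i0 = 0; i0 < d0; ++i0) {
      R_xlen_t base = i0 + (R_xlen_t)d0 * i1;
      bool any = false;
      for (int i2 = 0; i2 < d2; ++i2) {
        f[i2] = out[base + s2 * i2];
        if (f[i2] < DT_INF) any = true;
      }
      if (!any) continue;
      dt1d(f, d, v, z, d2);
      for (int i2 = 0; i2 < d2; ++i2) out[base + s2 * i2] = d[i2];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (out[i] == DT_INF) ? R_PosInf : std::sqrt(out[i]);
  return out;
}
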