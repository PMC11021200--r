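#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact anisotropic squared Euclidean distance transform (separable
// lower-envelope-of-parabolas algorithm applied along each axis in turn).
// Input: binary mask; output: squared distance in µm² from every voxel
// center to the nearest foreground voxel center.

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;  // only finite parabolas join the envelope
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      double xq = q * w, xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (k < 0) {  // no finite source in this line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_3d(IntegerVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] != 0 ? 0.0 : INF;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i2 = 0; i2 < n2; ++i2) {
      R_xlen_t base = (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3);
      bool any = false;
      for (int q = 0; q < n1; ++q) { f[q] = out[base + q]; if (f[q] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, n1, spacing[0]);
      for (int q = 0; q < n1; ++q) out[base + q] = d[q];
    }
  // axis 2 (stride n1)
  for (int i3 = 0; i3 < n3; ++i3)
    for (int i1 = 0; i1 < n1; ++i1) {
      R_xlen_t base = i1 + (R_xlen_t)n1 * n2 * i3;
      bool any = false;
      for (int q = 0; q < n2; ++q) {
        f[q] = out[base + (R_xlen_t)n1 * q];
        if (f[q] < INF) any = true;
      }
      if (!any) continue;
      dt1d(f, d, v, z, n2, spacing[1]);
      for (int q = 0; q < n2; ++q) out[base + (R_xlen_t)n1 * q] = d[q];
    }
  // axis 3 (stride n1*n2)
  const R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1) {
      R_xlen_t base = i1 + (R_xlen_t)n1 * i2;
      bool any = false;
      for (int q = 0; q < n3; ++q) { f[q] = out[base + s3 * q]; if (f[q] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, z, n3, spacing[2]);
      for (int q = 0; q < n3; ++q) out[base + s3 * q] = d[q];
    }
  return out;
}
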