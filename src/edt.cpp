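#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher 1D squared distance transform of a sampled
// function f at grid positions i*step (anisotropic voxel spacing).
static void dt1d(std::vector<double> &f, double step) {
  const int n = (int)f.size();
  if (n == 0) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qx = q * step;
    double s;
    for (;;) {
      double vx = v[k] * step;
      s = ((f[q] + qx * qx) - (f[v[k]] + vx * vx)) / (2.0 * qx - 2.0 * vx);
      if (k > 0 && s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qx = q * step;
    while (z[k + 1] < qx) ++k;
    double vx = v[k] * step;
    d[q] = (qx - vx) * (qx - vx) + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact Euclidean squared distance (mm^2) from every voxel of a 3D grid to
// the nearest TRUE voxel of `mask`, with per-axis voxel spacing. Column-major
// layout, dims = (d1, d2, d3). All-FALSE masks yield +Inf everywhere.
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  // large finite sentinel keeps the envelope arithmetic NaN-free; a voxel
  // keeps (approximately) this value only when the mask is entirely FALSE
  const double BIG = 1e30;
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    out[i] = mask[i] ? 0.0 : BIG;

  std::vector<double> line;
  // axis 1 (stride 1)
  line.resize(d1);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j) {
      R_xlen_t base = (R_xlen_t)k * d1 * d2 + (R_xlen_t)j * d1;
      for (int i = 0; i < d1; ++i) line[i] = out[base + i];
      dt1d(line, spacing[0]);
      for (int i = 0; i < d1; ++i) out[base + i] = line[i];
    }
  // axis 2 (stride d1)
  line.resize(d2);
  for (int k = 0; k < d3; ++k)
    for (int i = 0; i < d1; ++i) {
      R_xlen_t base = (R_xlen_t)k * d1 * d2 + i;
      for (int j = 0; j < d2; ++j) line[j] = out[base + (R_xlen_t)j * d1];
      dt1d(line, spacing[1]);
      for (int j = 0; j < d2; ++j) out[base + (R_xlen_t)j * d1] = line[j];
    }
  // axis 3 (stride d1*d2)
  line.resize(d3);
  for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      R_xlen_t base = (R_xlen_t)j * d1 + i;
      for (int k = 0; k < d3; ++k) line[k] = out[base + (R_xlen_t)k * d1 * d2];
      dt1d(line, spacing[2]);
      for (int k = 0; k < d3; ++k) out[base + (R_xlen_t)k * d1 * d2] = line[k];
    }
  return out;
}
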