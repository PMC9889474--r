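#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher exact squared Euclidean distance transform,
// one dimension at a time, in physical units (per-axis voxel spacing).

static const double INF = std::numeric_limits<double>::infinity();

// In-place 1D squared distance transform of sampled function f at
// positions 0, step, 2*step, ...
static void dt1d(std::vector<double>& f, double step,
                 std::vector<int>& v, std::vector<double>& z,
                 std::vector<double>& d) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double xq = q * step;
    double s;
    while (true) {
      int p = v[k];
      double xp = p * step;
      s = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2.0 * (xq - xp));
      if (s <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * step;
    while (z[k + 1] < xq) k++;
    double dx = xq - v[k] * step;
    d[q] = dx * dx + f[v[k]];
  }
  std::copy(d.begin(), d.end(), f.begin());
}

// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // large finite sentinel instead of Inf so parabola intersections stay
  // well-defined for empty lines
  const double BIG = 1e20;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along x
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      f.assign(out.begin() + base, out.begin() + base + nx);
      dt1d(f, spacing[0], v, z, d);
      std::copy(f.begin(), f.begin() + nx, out.begin() + base);
    }
  // along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)j * nx];
      f.resize(ny);
      dt1d(f, spacing[1], v, z, d);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)j * nx] = f[j];
      f.resize(nmax);
    }
  // along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; k++) f[k] = out[base + (R_xlen_t)k * nxy];
      f.resize(nz);
      dt1d(f, spacing[2], v, z, d);
      for (int k = 0; k < nz; k++) out[base + (R_xlen_t)k * nxy] = f[k];
      f.resize(nmax);
    }

  for (R_xlen_t i = 0; i < n; i++) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dim;
  return out;
}
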