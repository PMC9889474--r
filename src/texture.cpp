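#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gray-level co-occurrence and run-length matrices over the 13 unique 3D
// unit offsets. `levels` holds 1..nlev inside the mask, 0 outside.

// [[Rcpp::export(name = ".glcm_matrix_cpp")]]
NumericMatrix glcm_matrix_cpp(IntegerVector levels, IntegerVector dim,
                              int nlev, IntegerVector offset) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  NumericMatrix P(nlev, nlev);
  const int dx = offset[0], dy = offset[1], dz = offset[2];
  double tot = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        int a = levels[(R_xlen_t)k * nxy + (R_xlen_t)j * nx + i];
        if (a == 0) continue;
        int i2 = i + dx, j2 = j + dy, k2 = k + dz;
        if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
          continue;
        int b = levels[(R_xlen_t)k2 * nxy + (R_xlen_t)j2 * nx + i2];
        if (b == 0) continue;
        P(a - 1, b - 1) += 1;  // symmetrized below
        P(b - 1, a - 1) += 1;
        tot += 2;
      }
  if (tot > 0)
    for (int u = 0; u < nlev; u++)
      for (int v = 0; v < nlev; v++) P(u, v) /= tot;
  return P;
}

// [[Rcpp::export(name = ".glrlm_matrix_cpp")]]
NumericMatrix glrlm_matrix_cpp(IntegerVector levels, IntegerVector dim,
                               int nlev, IntegerVector direction) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const int dx = direction[0], dy = direction[1], dz = direction[2];
  int maxrun = std::max(nx, std::max(ny, nz));
  NumericMatrix R(nlev, maxrun);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t idx = (R_xlen_t)k * nxy + (R_xlen_t)j * nx + i;
        int a = levels[idx];
        if (a == 0) continue;
        // run starts here iff predecessor is outside grid/mask or differs
        int ip = i - dx, jp = j - dy, kp = k - dz;
        bool start = true;
        if (ip >= 0 && ip < nx && jp >= 0 && jp < ny && kp >= 0 && kp < nz) {
          int prev = levels[(R_xlen_t)kp * nxy + (R_xlen_t)jp * nx + ip];
          if (prev == a) start = false;
        }
        if (!start) continue;
        int len = 1;
        int i2 = i + dx, j2 = j + dy, k2 = k + dz;
        while (i2 >= 0 && i2 < nx && j2 >= 0 && j2 < ny && k2 >= 0 &&
               k2 < nz &&
               levels[(R_xlen_t)k2 * nxy + (R_xlen_t)j2 * nx + i2] == a) {
          len++;
          i2 += dx; j2 += dy; k2 += dz;
        }
        R(a - 1, len - 1) += 1;
      }
  return R;
}
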