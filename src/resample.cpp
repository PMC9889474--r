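#include <Rcpp.h>
using namespace Rcpp;

// Resampling on voxel-center convention: world = origin + index * spacing
// (0-based indices). Output grids share the input origin.

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// [[Rcpp::export(name = ".resample_cpp")]]
NumericVector resample_cpp(NumericVector values, IntegerVector dim,
                           NumericVector spacing, IntegerVector out_dim,
                           NumericVector out_spacing, bool nearest) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  NumericVector out((R_xlen_t)ox * oy * oz);

  for (int k = 0; k < oz; k++) {
    double wz = k * out_spacing[2] / spacing[2];
    for (int j = 0; j < oy; j++) {
      double wy = j * out_spacing[1] / spacing[1];
      for (int i = 0; i < ox; i++) {
        double wx = i * out_spacing[0] / spacing[0];
        R_xlen_t oidx = (R_xlen_t)k * ox * oy + (R_xlen_t)j * ox + i;
        if (nearest) {
          int ix = (int)clampd(std::round(wx), 0, nx - 1);
          int iy = (int)clampd(std::round(wy), 0, ny - 1);
          int iz = (int)clampd(std::round(wz), 0, nz - 1);
          out[oidx] = values[(R_xlen_t)iz * nxy + (R_xlen_t)iy * nx + ix];
        } else {
          double cx = clampd(wx, 0, nx - 1);
          double cy = clampd(wy, 0, ny - 1);
          double cz = clampd(wz, 0, nz - 1);
          int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy),
              z0 = (int)std::floor(cz);
          int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
              z1 = std::min(z0 + 1, nz - 1);
          double fx = cx - x0, fy = cy - y0, fz = cz - z0;
          double c000 = values[(R_xlen_t)z0 * nxy + (R_xlen_t)y0 * nx + x0];
          double c100 = values[(R_xlen_t)z0 * nxy + (R_xlen_t)y0 * nx + x1];
          double c010 = values[(R_xlen_t)z0 * nxy + (R_xlen_t)y1 * nx + x0];
          double c110 = values[(R_xlen_t)z0 * nxy + (R_xlen_t)y1 * nx + x1];
          double c001 = values[(R_xlen_t)z1 * nxy + (R_xlen_t)y0 * nx + x0];
          double c101 = values[(R_xlen_t)z1 * nxy + (R_xlen_t)y0 * nx + x1];
          double c011 = values[(R_xlen_t)z1 * nxy + (R_xlen_t)y1 * nx + x0];
          double c111 = values[(R_xlen_t)z1 * nxy + (R_xlen_t)y1 * nx + x1];
          double c00 = c000 * (1 - fx) + c100 * fx;
          double c10 = c010 * (1 - fx) + c110 * fx;
          double c01 = c001 * (1 - fx) + c101 * fx;
          double c11 = c011 * (1 - fx) + c111 * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          out[oidx] = c0 * (1 - fz) + c1 * fz;
        }
      }
    }
  }
  out.attr("dim") = out_dim;
  return out;
}

// Separable Gaussian blur, sigma per axis in voxel units, reflected borders.
// [[Rcpp::export(name = ".gaussian_blur_cpp")]]
NumericVector gaussian_blur_cpp(NumericVector values, IntegerVector dim,
                                NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  NumericVector cur = clone(values);

  for (int ax = 0; ax < 3; ax++) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int rad = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> kern(2 * rad + 1);
    double ksum = 0;
    for (int t = -rad; t <= rad; t++) {
      kern[t + rad] = std::exp(-0.5 * t * t / (s * s));
      ksum += kern[t + rad];
    }
    for (auto& kv : kern) kv /= ksum;

    NumericVector nxt((R_xlen_t)nx * ny * nz);
    int len = ax == 0 ? nx : (ax == 1 ? ny : nz);
    R_xlen_t stride = ax == 0 ? 1 : (ax == 1 ? nx : nxy);
    // iterate over all lines along axis ax
    for (int k = 0; k < (ax == 2 ? 1 : nz); k++) {
      for (int j = 0; j < (ax == 1 ? 1 : ny); j++) {
        for (int i = 0; i < (ax == 0 ? 1 : nx); i++) {
          R_xlen_t base = (R_xlen_t)k * nxy + (R_xlen_t)j * nx + i;
          for (int p = 0; p < len; p++) {
            double acc = 0;
            for (int t = -rad; t <= rad; t++) {
              int q = p + t;
              if (q < 0) q = -q;                    // reflect
              if (q >= len) q = 2 * len - 2 - q;
              if (q < 0) q = 0;
              acc += kern[t + rad] * cur[base + (R_xlen_t)q * stride];
            }
            nxt[base + (R_xlen_t)p * stride] = acc;
          }
        }
      }
    }
    cur = nxt;
  }
  cur.attr("dim") = dim;
  return cur;
}
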