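#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Isosurface (level 0.5) of a scalar field by marching tetrahedra:
// each cube is split into 6 tetrahedra sharing the main diagonal; triangle
// vertices are linearly interpolated on tetrahedron edges. Returns total
// surface area and enclosed volume (divergence theorem, outward normals).

struct V3 { double x, y, z; };

static inline V3 vsub(const V3& a, const V3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline V3 vcross(const V3& a, const V3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
static inline double vdot(const V3& a, const V3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

static inline V3 interp(const V3& p, const V3& q, double fp, double fq) {
  double t = (0.5 - fp) / (fq - fp);
  return {p.x + t * (q.x - p.x), p.y + t * (q.y - p.y),
          p.z + t * (q.z - p.z)};
}

// [[Rcpp::export(name = ".mesh_area_volume_cpp")]]
NumericVector mesh_area_volume_cpp(NumericVector field, IntegerVector dim,
                                   NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  // corner offsets of the unit cube
  static const int co[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                               {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // 6 tetrahedra sharing diagonal c0-c6
  static const int tets[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},
                                 {0,7,4,6},{0,4,5,6},{0,5,1,6}};
  double area = 0, vol = 0;

  for (int k = 0; k < nz - 1; k++)
    for (int j = 0; j < ny - 1; j++)
      for (int i = 0; i < nx - 1; i++) {
        double f[8];
        V3 p[8];
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; c++) {
          int ci = i + co[c][0], cj = j + co[c][1], ck = k + co[c][2];
          f[c] = field[(R_xlen_t)ck * nxy + (R_xlen_t)cj * nx + ci];
          p[c] = {ci * spacing[0], cj * spacing[1], ck * spacing[2]};
          if (f[c] > 0.5) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;

        for (int t = 0; t < 6; t++) {
          int vi[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; c++) {
            if (f[vi[c]] > 0.5) in[nin++] = vi[c];
            else out[nout++] = vi[c];
          }
          if (nin == 0 || nin == 4) continue;

          V3 tris[2][3];
          int ntri = 0;
          if (nin == 1) {
            tris[0][0] = interp(p[in[0]], p[out[0]], f[in[0]], f[out[0]]);
            tris[0][1] = interp(p[in[0]], p[out[1]], f[in[0]], f[out[1]]);
            tris[0][2] = interp(p[in[0]], p[out[2]], f[in[0]], f[out[2]]);
            ntri = 1;
          } else if (nin == 3) {
            tris[0][0] = interp(p[in[0]], p[out[0]], f[in[0]], f[out[0]]);
            tris[0][1] = interp(p[in[1]], p[out[0]], f[in[1]], f[out[0]]);
            tris[0][2] = interp(p[in[2]], p[out[0]], f[in[2]], f[out[0]]);
            ntri = 1;
          } else {  // 2 in, 2 out: quad AC, AD, BD, BC
            V3 AC = interp(p[in[0]], p[out[0]], f[in[0]], f[out[0]]);
            V3 AD = interp(p[in[0]], p[out[1]], f[in[0]], f[out[1]]);
            V3 BD = interp(p[in[1]], p[out[1]], f[in[1]], f[out[1]]);
            V3 BC = interp(p[in[1]], p[out[0]], f[in[1]], f[out[0]]);
            tris[0][0] = AC; tris[0][1] = AD; tris[0][2] = BD;
            tris[1][0] = AC; tris[1][1] = BD; tris[1][2] = BC;
            ntri = 2;
          }

          // orient normals from inside toward outside
          V3 cin = {0, 0, 0}, cout = {0, 0, 0};
          for (int c = 0; c < nin; c++) {
            cin.x += p[in[c]].x / nin; cin.y += p[in[c]].y / nin;
            cin.z += p[in[c]].z / nin;
          }
          for (int c = 0; c < nout; c++) {
            cout.x += p[out[c]].x / nout; cout.y += p[out[c]].y / nout;
            cout.z += p[out[c]].z / nout;
          }
          V3 dir = vsub(cout, cin);

          for (int tr = 0; tr < ntri; tr++) {
            V3 a = tris[tr][0], b = tris[tr][1], c = tris[tr][2];
            V3 n = vcross(vsub(b, a), vsub(c, a));
            if (vdot(n, dir) < 0) { V3 tmp = b; b = c; c = tmp;
                                    n = vcross(vsub(b, a), vsub(c, a)); }
            double a2 = std::sqrt(vdot(n, n));
            area += 0.5 * a2;
            vol += vdot(a, vcross(b, c)) / 6.0;
          }
        }
      }

  return NumericVector::create(area, std::fabs(vol));
}

// Maximum pairwise distance between surface voxel centers (physical units).
// [[Rcpp::export(name = ".max_diameter_cpp")]]
double max_diameter_cpp(NumericMatrix coords) {
  const int n = coords.nrow();
  double best = 0;
  for (int i = 0; i < n; i++)
    for (int j = i + 1; j < n; j++) {
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
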