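#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Voxelize a closed triangle soup by parity of ray crossings.
//
// tris: ntri x 9 matrix, each row (x1,y1,z1,x2,y2,z2,x3,y3,z3) in
// *continuous 0-based voxel coordinates* (caller converts from world).
// Rays run along +z through every voxel-center column (ix, iy); sample
// points are offset by a tiny fraction of a voxel so rays never hit
// triangle edges or vertices exactly, keeping the parity rule stable and
// deterministic. Columns with an odd crossing count (possible only for
// open or degenerate input) drop their last crossing.
// [[Rcpp::export]]
IntegerVector raster_parity(NumericMatrix tris, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double ex = 2.33e-7, ey = 1.07e-7;  // sub-voxel ray offsets
  IntegerVector mask(nx * ny * nz, 0);
  std::vector< std::vector<double> > crossings((size_t)nx * ny);

  for (int t = 0; t < tris.nrow(); ++t) {
    double x1 = tris(t, 0), y1 = tris(t, 1), z1 = tris(t, 2);
    double x2 = tris(t, 3), y2 = tris(t, 4), z2 = tris(t, 5);
    double x3 = tris(t, 6), y3 = tris(t, 7), z3 = tris(t, 8);
    double den = (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3);
    if (std::fabs(den) < 1e-14) continue;  // projects to a line: no area
    int ix0 = (int)std::ceil(std::min(x1, std::min(x2, x3)) - ex);
    int ix1 = (int)std::floor(std::max(x1, std::max(x2, x3)) - ex);
    int iy0 = (int)std::ceil(std::min(y1, std::min(y2, y3)) - ey);
    int iy1 = (int)std::floor(std::max(y1, std::max(y2, y3)) - ey);
    ix0 = std::max(ix0, 0); ix1 = std::min(ix1, nx - 1);
    iy0 = std::max(iy0, 0); iy1 = std::min(iy1, ny - 1);
    for (int iy = iy0; iy <= iy1; ++iy) {
      double sy = iy + ey;
      for (int ix = ix0; ix <= ix1; ++ix) {
        double sx = ix + ex;
        double l1 = ((y2 - y3) * (sx - x3) + (x3 - x2) * (sy - y3)) / den;
        double l2 = ((y3 - y1) * (sx - x3) + (x1 - x3) * (sy - y3)) / den;
        double l3 = 1.0 - l1 - l2;
        if (l1 <= 0.0 || l2 <= 0.0 || l3 <= 0.0) continue;
        crossings[(size_t)iy * nx + ix].push_back(l1 * z1 + l2 * z2 + l3 * z3);
      }
    }
  }

  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      std::vector<double> &zs = crossings[(size_t)iy * nx + ix];
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      size_t npair = zs.size() / 2;
      for (size_t k = 0; k < npair; ++k) {
        double zin = zs[2 * k], zout = zs[2 * k + 1];
        int k0 = (int)std::ceil(zin), k1 = (int)std::floor(zout);
        // exclude centers exactly on the surface (measure zero anyway)
        if ((double)k0 == zin) ++k0;
        if ((double)k1 == zout) --k1;
        k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
        for (int iz = k0; iz <= k1; ++iz)
          mask[(size_t)iz * nx * ny + (size_t)iy * nx + ix] = 1;
      }
    }
  }
  return mask;
}

static inline void closest_on_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out) {
  // Ericson, Real-Time Collision Detection, closest point on triangle.
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// Nearest points on a triangle soup for each query point (brute force).
// points: n x 3; tris: m x 9. Returns n x 4: the closest point and the
// 1-based index of the triangle realizing it.
// [[Rcpp::export]]
NumericMatrix project_to_surface(NumericMatrix points, NumericMatrix tris) {
  int n = points.nrow(), m = tris.nrow();
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    double p[3] = { points(i, 0), points(i, 1), points(i, 2) };
    double best = R_PosInf, bestq[3] = { p[0], p[1], p[2] };
    int bestt = 0;
    for (int t = 0; t < m; ++t) {
      double a[3] = { tris(t, 0), tris(t, 1), tris(t, 2) };
      double b[3] = { tris(t, 3), tris(t, 4), tris(t, 5) };
      double c[3] = { tris(t, 6), tris(t, 7), tris(t, 8) };
      double q[3];
      closest_on_triangle(p, a, b, c, q);
      double d2 = (q[0]-p[0])*(q[0]-p[0]) + (q[1]-p[1])*(q[1]-p[1]) +
                  (q[2]-p[2])*(q[2]-p[2]);
      if (d2 < best) {
        best = d2; bestq[0] = q[0]; bestq[1] = q[1]; bestq[2] = q[2];
        bestt = t;
      }
    }
    out(i, 0) = bestq[0]; out(i, 1) = bestq[1]; out(i, 2) = bestq[2];
    out(i, 3) = bestt + 1;
  }
  return out;
}
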