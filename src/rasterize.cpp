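#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Rasterize a closed triangulated surface given in continuous 0-based voxel
// coordinates onto a (nx,ny,nz) grid: voxel centers at integer coordinates,
// inside test by counting ray crossings along +z per (i,j) column. Rays are
// jittered by a small irrational offset so that hits on triangle edges are
// measure-zero.
// [[Rcpp::export]]
IntegerVector cpp_rasterize(NumericMatrix verts, IntegerMatrix tris,
                            IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double ex = 1.0e-4, ey = 2.236e-4;  // ray jitter
  std::vector<std::vector<double>> cross((size_t)nx * ny);
  int nt = tris.nrow();
  for (int t = 0; t < nt; ++t) {
    const int i0 = tris(t, 0), i1 = tris(t, 1), i2 = tris(t, 2);
    double ax = verts(i0, 0), ay = verts(i0, 1), az = verts(i0, 2);
    double bx = verts(i1, 0), by = verts(i1, 1), bz = verts(i1, 2);
    double cx = verts(i2, 0), cy = verts(i2, 1), cz = verts(i2, 2);
    int xmin = std::max(0, (int)std::floor(std::min({ax, bx, cx})) - 1);
    int xmax = std::min(nx - 1, (int)std::ceil(std::max({ax, bx, cx})) + 1);
    int ymin = std::max(0, (int)std::floor(std::min({ay, by, cy})) - 1);
    int ymax = std::min(ny - 1, (int)std::ceil(std::max({ay, by, cy})) + 1);
    double d00x = bx - ax, d00y = by - ay;
    double d01x = cx - ax, d01y = cy - ay;
    double det = d00x * d01y - d01x * d00y;
    if (std::fabs(det) < 1e-14) continue;  // vertical triangle: no xy area
    for (int j = ymin; j <= ymax; ++j)
      for (int i = xmin; i <= xmax; ++i) {
        double px = i + ex - ax, py = j + ey - ay;
        double u = (px * d01y - d01x * py) / det;
        double v = (d00x * py - px * d00y) / det;
        if (u < 0 || v < 0 || u + v > 1) continue;
        double z = az + u * (bz - az) + v * (cz - az);
        cross[(size_t)i + (size_t)nx * j].push_back(z);
      }
  }
  IntegerVector out((R_xlen_t)nx * ny * nz);
  out.attr("dim") = dim;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      auto &zs = cross[(size_t)i + (size_t)nx * j];
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      // fill between successive pairs of crossings
      for (size_t p = 0; p + 1 < zs.size(); p += 2) {
        int k0 = (int)std::ceil(zs[p]);
        int k1 = (int)std::floor(zs[p + 1]);
        for (int k = std::max(0, k0); k <= std::min(nz - 1, k1); ++k)
          out[i + (R_xlen_t)nx * j + (R_xlen_t)nx * ny * k] = 1;
      }
    }
  return out;
}
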