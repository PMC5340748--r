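#include <Rcpp.h>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Separable Gaussian smoothing of a 3D array; sigma per axis in voxel units;
// replicate boundary. sigma <= 0 leaves that axis untouched.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth3(NumericVector arr, IntegerVector dim,
                                NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(arr.begin(), arr.end()), b(a.size());
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> w(2 * r + 1);
    double tot = 0;
    for (int i = -r; i <= r; ++i) {
      w[i + r] = std::exp(-0.5 * i * i / (s * s));
      tot += w[i + r];
    }
    for (auto &v : w) v /= tot;
    int n[3] = {nx, ny, nz};
    int stride[3] = {1, nx, nx * ny};
    int st = stride[axis], len = n[axis];
    // iterate over all lines along 'axis'
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int idx3[3] = {i, j, k};
          if (idx3[axis] != 0) continue;  // start of a line only
          long base = i + (long)nx * j + (long)nx * ny * k;
          for (int p = 0; p < len; ++p) {
            double acc = 0;
            for (int q = -r; q <= r; ++q) {
              int pp = clampi(p + q, 0, len - 1);
              acc += w[q + r] * a[base + (long)st * pp];
            }
            b[base + (long)st * p] = acc;
          }
        }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Trilinear sampling of a 3D array at continuous 0-based voxel coordinates.
// Points outside the grid return 'fill'.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector arr, IntegerVector dim,
                            NumericMatrix pts, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[p] = fill;
      continue;
    }
    int i = (int)std::floor(x), j = (int)std::floor(y), k = (int)std::floor(z);
    if (i == nx - 1) i--;
    if (j == ny - 1) j--;
    if (k == nz - 1) k--;
    double fx = x - i, fy = y - j, fz = z - k;
    double acc = 0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dxx = 0; dxx < 2; ++dxx) {
          double w = (dxx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                     (dz ? fz : 1 - fz);
          acc += w * arr[(i + dxx) + (long)nx * (j + dy) +
                         (long)nx * ny * (k + dz)];
        }
    out[p] = acc;
  }
  return out;
}

// Nearest-neighbour sampling (for label maps).
// [[Rcpp::export]]
NumericVector cpp_nearest(NumericVector arr, IntegerVector dim,
                          NumericMatrix pts, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int np = pts.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    int i = (int)std::lround(pts(p, 0));
    int j = (int)std::lround(pts(p, 1));
    int k = (int)std::lround(pts(p, 2));
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
      out[p] = fill;
    else
      out[p] = arr[i + (long)nx * j + (long)nx * ny * k];
  }
  return out;
}

// Central-difference gradient (voxel units); one-sided at borders.
// [[Rcpp::export]]
List cpp_gradient3(NumericVector arr, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector gx(arr.size()), gy(arr.size()), gz(arr.size());
  auto at = [&](int i, int j, int k) {
    return arr[i + (long)nx * j + (long)nx * ny * k];
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long id = i + (long)nx * j + (long)nx * ny * k;
        int i0 = clampi(i - 1, 0, nx - 1), i1 = clampi(i + 1, 0, nx - 1);
        int j0 = clampi(j - 1, 0, ny - 1), j1 = clampi(j + 1, 0, ny - 1);
        int k0 = clampi(k - 1, 0, nz - 1), k1 = clampi(k + 1, 0, nz - 1);
        gx[id] = (at(i1, j, k) - at(i0, j, k)) / std::max(1, i1 - i0);
        gy[id] = (at(i, j1, k) - at(i, j0, k)) / std::max(1, j1 - j0);
        gz[id] = (at(i, j, k1) - at(i, j, k0)) / std::max(1, k1 - k0);
      }
  gx.attr("dim") = dim;
  gy.attr("dim") = dim;
  gz.attr("dim") = dim;
  return List::create(_["x"] = gx, _["y"] = gy, _["z"] = gz);
}
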