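#include <Rcpp.h>
using namespace Rcpp;

// Closest squared distance from point p to triangle (a,b,c).
// Plane projection with barycentric clamp; falls back to edge distances.
static double pt_tri_dist2(const double *p, const double *a, const double *b,
                           const double *c) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d00 = 0, d01 = 0, d11 = 0, d20 = 0, d21 = 0;
  for (int k = 0; k < 3; ++k) {
    d00 += ab[k] * ab[k];
    d01 += ab[k] * ac[k];
    d11 += ac[k] * ac[k];
    d20 += ap[k] * ab[k];
    d21 += ap[k] * ac[k];
  }
  double denom = d00 * d11 - d01 * d01;
  double u = -1, v = -1;
  if (denom > 1e-30) {
    u = (d11 * d20 - d01 * d21) / denom;
    v = (d00 * d21 - d01 * d20) / denom;
  }
  if (u >= 0 && v >= 0 && u + v <= 1) {
    double q[3], d2 = 0;
    for (int k = 0; k < 3; ++k) {
      q[k] = a[k] + u * ab[k] + v * ac[k];
      d2 += (p[k] - q[k]) * (p[k] - q[k]);
    }
    return d2;
  }
  // clamp to the three edges
  auto seg = [&](const double *s, const double *e) {
    double se[3], sp[3], L = 0, t = 0;
    for (int k = 0; k < 3; ++k) {
      se[k] = e[k] - s[k];
      sp[k] = p[k] - s[k];
      L += se[k] * se[k];
      t += sp[k] * se[k];
    }
    t = (L > 1e-30) ? t / L : 0.0;
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    double d2 = 0;
    for (int k = 0; k < 3; ++k) {
      double q = s[k] + t * se[k];
      d2 += (p[k] - q) * (p[k] - q);
    }
    return d2;
  };
  double d2 = seg(a, b);
  double e2 = seg(a, c);
  if (e2 < d2) d2 = e2;
  e2 = seg(b, c);
  if (e2 < d2) d2 = e2;
  return d2;
}

// [[Rcpp::export]]
NumericVector cpp_point_triangle_dist(NumericMatrix pts, NumericMatrix verts,
                                      IntegerMatrix tris) {
  int np = pts.nrow(), nt = tris.nrow();
  NumericVector out(np);
  std::vector<double> V(verts.nrow() * 3);
  for (int i = 0; i < verts.nrow(); ++i)
    for (int k = 0; k < 3; ++k) V[3 * i + k] = verts(i, k);
  for (int i = 0; i < np; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double best = R_PosInf;
    for (int t = 0; t < nt; ++t) {
      const double *a = &V[3 * tris(t, 0)];
      const double *b = &V[3 * tris(t, 1)];
      const double *c = &V[3 * tris(t, 2)];
      double d2 = pt_tri_dist2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Index (1-based) and distance of the nearest row of 'verts' for each point.
// [[Rcpp::export]]
List cpp_nearest_vertex(NumericMatrix pts, NumericMatrix verts) {
  int np = pts.nrow(), nv = verts.nrow();
  IntegerVector idx(np);
  NumericVector dist(np);
  for (int i = 0; i < np; ++i) {
    double best = R_PosInf;
    int bj = 0;
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    for (int j = 0; j < nv; ++j) {
      double dx = x - verts(j, 0), dy = y - verts(j, 1), dz = z - verts(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
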