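#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Isosurface of a 3D scalar array by marching tetrahedra: each cube is split
// into 6 Kuhn tetrahedra, each tetrahedron contributes 0/1/2 triangles with
// vertices linearly interpolated on its edges at 'level'. Output vertices in
// continuous 0-based voxel coordinates; triangles 0-based, oriented so that
// normals point from values > level toward values < level (outward for a
// binary mask).
// [[Rcpp::export]]
List cpp_march_tets(NumericVector arr, IntegerVector dim, double level) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  auto val = [&](int i, int j, int k) {
    return arr[i + (long)nx * j + (long)nx * ny * k];
  };
  auto gid = [&](int i, int j, int k) {
    return (long long)i + (long long)nx * (j + (long long)ny * k);
  };
  static const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                  {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  std::unordered_map<long long, int> edge_vertex;
  std::vector<double> V;   // xyz triplets
  std::vector<int> T;      // index triplets
  long long NN = (long long)nx * ny * nz;
  // interpolated vertex on the edge between nodes A and B (grid coords)
  auto edge_pt = [&](const int A[3], const int B[3]) -> int {
    long long ga = gid(A[0], A[1], A[2]), gb = gid(B[0], B[1], B[2]);
    long long key = ga < gb ? ga * NN + gb : gb * NN + ga;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double va = val(A[0], A[1], A[2]), vb = val(B[0], B[1], B[2]);
    double t = (level - va) / (vb - va);
    int id = (int)(V.size() / 3);
    for (int q = 0; q < 3; ++q) V.push_back(A[q] + t * (B[q] - A[q]));
    edge_vertex[key] = id;
    return id;
  };
  auto emit = [&](int a, int b, int c, const double din[3]) {
    // din: direction from inside toward outside; normal must align with it
    double e1[3], e2[3], n[3];
    for (int q = 0; q < 3; ++q) {
      e1[q] = V[3 * b + q] - V[3 * a + q];
      e2[q] = V[3 * c + q] - V[3 * a + q];
    }
    n[0] = e1[1] * e2[2] - e1[2] * e2[1];
    n[1] = e1[2] * e2[0] - e1[0] * e2[2];
    n[2] = e1[0] * e2[1] - e1[1] * e2[0];
    double d = n[0] * din[0] + n[1] * din[1] + n[2] * din[2];
    T.push_back(a);
    if (d >= 0) {
      T.push_back(b);
      T.push_back(c);
    } else {
      T.push_back(c);
      T.push_back(b);
    }
  };
  int tet[4][3];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        for (int p = 0; p < 6; ++p) {
          tet[0][0] = i; tet[0][1] = j; tet[0][2] = k;
          for (int s = 1; s < 4; ++s) {
            for (int q = 0; q < 3; ++q) tet[s][q] = tet[s - 1][q];
            tet[s][perms[p][s - 1]] += 1;
          }
          bool in[4];
          int nin = 0;
          for (int s = 0; s < 4; ++s) {
            in[s] = val(tet[s][0], tet[s][1], tet[s][2]) > level;
            if (in[s]) nin++;
          }
          if (nin == 0 || nin == 4) continue;
          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0}, din[3];
          for (int s = 0; s < 4; ++s)
            for (int q = 0; q < 3; ++q)
              (in[s] ? cin[q] : cout[q]) += tet[s][q];
          for (int q = 0; q < 3; ++q)
            din[q] = cout[q] / (4 - nin) - cin[q] / nin;
          if (nin == 1 || nin == 3) {
            int s0 = -1;
            for (int s = 0; s < 4; ++s)
              if (in[s] == (nin == 1)) s0 = s;
            int e[3], m = 0;
            for (int s = 0; s < 4; ++s)
              if (s != s0) e[m++] = edge_pt(tet[s0], tet[s]);
            emit(e[0], e[1], e[2], din);
          } else {  // nin == 2: quad split into two triangles
            int ia = -1, ib = -1, oc = -1, od = -1;
            for (int s = 0; s < 4; ++s) {
              if (in[s]) { if (ia < 0) ia = s; else ib = s; }
              else { if (oc < 0) oc = s; else od = s; }
            }
            int eac = edge_pt(tet[ia], tet[oc]);
            int ead = edge_pt(tet[ia], tet[od]);
            int ebd = edge_pt(tet[ib], tet[od]);
            int ebc = edge_pt(tet[ib], tet[oc]);
            emit(eac, ead, ebd, din);
            emit(eac, ebd, ebc, din);
          }
        }
      }
  int nv = (int)(V.size() / 3), nt = (int)(T.size() / 3);
  NumericMatrix verts(nv, 3);
  IntegerMatrix tris(nt, 3);
  for (int a = 0; a < nv; ++a)
    for (int q = 0; q < 3; ++q) verts(a, q) = V[3 * a + q];
  for (int t = 0; t < nt; ++t)
    for (int q = 0; q < 3; ++q) tris(t, q) = T[3 * t + q];
  return List::create(_["vertices"] = verts, _["triangles"] = tris);
}
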