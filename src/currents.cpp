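#include <Rcpp.h>
using namespace Rcpp;

// Currents inner product S(P,Q) = sum_ij exp(-|c_i - c_j|^2 / lw^2) (n_i . n_j)
// over triangle centers c and area-weighted normals n.
static void flatten(const NumericMatrix &m, std::vector<double> &out) {
  int n = m.nrow();
  out.resize(3 * n);
  for (int i = 0; i < n; ++i)
    for (int q = 0; q < 3; ++q) out[3 * i + q] = m(i, q);
}

// exp(-u) with a cutoff: beyond 30 the kernel is ~1e-13 and skipped
static inline double kexp(double u) { return u > 30.0 ? 0.0 : std::exp(-u); }

// [[Rcpp::export]]
double cpp_currents_product(NumericMatrix c1, NumericMatrix n1,
                            NumericMatrix c2, NumericMatrix n2,
                            double lambda) {
  int a = c1.nrow(), b = c2.nrow();
  double il2 = 1.0 / (lambda * lambda), s = 0.0;
  std::vector<double> C1, N1, C2, N2;
  flatten(c1, C1);
  flatten(n1, N1);
  flatten(c2, C2);
  flatten(n2, N2);
  bool same = (a == b);
  if (same)
    for (int i = 0; i < 3 * a && same; ++i)
      if (C1[i] != C2[i] || N1[i] != N2[i]) same = false;
  if (same) {
    for (int i = 0; i < a; ++i) {
      const double *ci = &C1[3 * i], *ni = &N1[3 * i];
      s += ni[0] * ni[0] + ni[1] * ni[1] + ni[2] * ni[2];
      double srow = 0.0;
      for (int j = i + 1; j < a; ++j) {
        const double *cj = &C1[3 * j], *nj = &N1[3 * j];
        double dx = ci[0] - cj[0], dy = ci[1] - cj[1], dz = ci[2] - cj[2];
        double k = kexp((dx * dx + dy * dy + dz * dz) * il2);
        if (k > 0)
          srow += k * (ni[0] * nj[0] + ni[1] * nj[1] + ni[2] * nj[2]);
      }
      s += 2.0 * srow;
    }
    return s;
  }
  for (int i = 0; i < a; ++i) {
    const double *ci = &C1[3 * i], *ni = &N1[3 * i];
    for (int j = 0; j < b; ++j) {
      const double *cj = &C2[3 * j], *nj = &N2[3 * j];
      double dx = ci[0] - cj[0], dy = ci[1] - cj[1], dz = ci[2] - cj[2];
      double k = kexp((dx * dx + dy * dy + dz * dz) * il2);
      if (k > 0)
        s += k * (ni[0] * nj[0] + ni[1] * nj[1] + ni[2] * nj[2]);
    }
  }
  return s;
}

// Energy E(A) = S(A,A) - 2 S(A,B) + sBB and its gradient with respect to the
// vertices of A. B enters through fixed centers/normals.
// [[Rcpp::export]]
List cpp_currents_energy_grad(NumericMatrix vA, IntegerMatrix tA,
                              NumericMatrix cB, NumericMatrix nB,
                              double sBB, double lambda) {
  int nT = tA.nrow(), nV = vA.nrow(), nTB = cB.nrow();
  double il2 = 1.0 / (lambda * lambda);
  // centers and area-weighted normals of A
  std::vector<double> cA(3 * nT), nA(3 * nT);
  for (int t = 0; t < nT; ++t) {
    int i0 = tA(t, 0), i1 = tA(t, 1), i2 = tA(t, 2);
    double e1[3], e2[3];
    for (int k = 0; k < 3; ++k) {
      cA[3 * t + k] = (vA(i0, k) + vA(i1, k) + vA(i2, k)) / 3.0;
      e1[k] = vA(i1, k) - vA(i0, k);
      e2[k] = vA(i2, k) - vA(i0, k);
    }
    nA[3 * t + 0] = 0.5 * (e1[1] * e2[2] - e1[2] * e2[1]);
    nA[3 * t + 1] = 0.5 * (e1[2] * e2[0] - e1[0] * e2[2]);
    nA[3 * t + 2] = 0.5 * (e1[0] * e2[1] - e1[1] * e2[0]);
  }
  double sAA = 0.0, sAB = 0.0;
  std::vector<double> gC(3 * nT, 0.0), gN(3 * nT, 0.0);
  std::vector<double> CB, NB;
  flatten(cB, CB);
  flatten(nB, NB);
  for (int i = 0; i < nT; ++i) {
    double ci[3] = {cA[3 * i], cA[3 * i + 1], cA[3 * i + 2]};
    double ni[3] = {nA[3 * i], nA[3 * i + 1], nA[3 * i + 2]};
    for (int j = 0; j < nT; ++j) {
      double d[3] = {ci[0] - cA[3 * j], ci[1] - cA[3 * j + 1],
                     ci[2] - cA[3 * j + 2]};
      double k = kexp((d[0] * d[0] + d[1] * d[1] + d[2] * d[2]) * il2);
      if (k == 0) continue;
      double dot = ni[0] * nA[3 * j] + ni[1] * nA[3 * j + 1] +
                   ni[2] * nA[3 * j + 2];
      sAA += k * dot;
      // dE/dn_i from S(A,A): 2 * sum_j K n_j ; dE/dc_i: 2 * sum_j dot * dK/dc_i
      double w = -2.0 * il2 * k * dot * 2.0;  // includes outer factor 2
      for (int q = 0; q < 3; ++q) {
        gN[3 * i + q] += 2.0 * k * nA[3 * j + q];
        gC[3 * i + q] += w * d[q];
      }
    }
    for (int j = 0; j < nTB; ++j) {
      double d[3] = {ci[0] - CB[3 * j], ci[1] - CB[3 * j + 1],
                     ci[2] - CB[3 * j + 2]};
      double k = kexp((d[0] * d[0] + d[1] * d[1] + d[2] * d[2]) * il2);
      if (k == 0) continue;
      double dot = ni[0] * NB[3 * j] + ni[1] * NB[3 * j + 1] +
                   ni[2] * NB[3 * j + 2];
      sAB += k * dot;
      double w = -2.0 * il2 * k * dot * (-2.0);  // outer factor -2
      for (int q = 0; q < 3; ++q) {
        gN[3 * i + q] += -2.0 * k * NB[3 * j + q];
        gC[3 * i + q] += w * d[q];
      }
    }
  }
  // chain rule to vertices: c = (v0+v1+v2)/3 ; n = 0.5 (v1-v0) x (v2-v0)
  NumericMatrix grad(nV, 3);
  for (int t = 0; t < nT; ++t) {
    int i0 = tA(t, 0), i1 = tA(t, 1), i2 = tA(t, 2);
    double g[3] = {gN[3 * t], gN[3 * t + 1], gN[3 * t + 2]};
    double e1[3], e2[3];
    for (int k = 0; k < 3; ++k) {
      e1[k] = vA(i1, k) - vA(i0, k);
      e2[k] = vA(i2, k) - vA(i0, k);
    }
    // d(g.n)/dv1 = 0.5 e2 x g ; d(g.n)/dv2 = 0.5 g x e1 ; dv0 = -(sum)
    double g1[3] = {0.5 * (e2[1] * g[2] - e2[2] * g[1]),
                    0.5 * (e2[2] * g[0] - e2[0] * g[2]),
                    0.5 * (e2[0] * g[1] - e2[1] * g[0])};
    double g2[3] = {0.5 * (g[1] * e1[2] - g[2] * e1[1]),
                    0.5 * (g[2] * e1[0] - g[0] * e1[2]),
                    0.5 * (g[0] * e1[1] - g[1] * e1[0])};
    for (int k = 0; k < 3; ++k) {
      double gc = gC[3 * t + k] / 3.0;
      grad(i0, k) += gc - g1[k] - g2[k];
      grad(i1, k) += gc + g1[k];
      grad(i2, k) += gc + g2[k];
    }
  }
  double energy = sAA - 2.0 * sAB + sBB;
  return List::create(_["energy"] = energy, _["sAA"] = sAA, _["sAB"] = sAB,
                      _["grad"] = grad);
}
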