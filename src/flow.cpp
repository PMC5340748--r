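#include <Rcpp.h>
using namespace Rcpp;

// Forward Euler integration of dx/dt = sum_k exp(-|x-c_k|^2/lv^2) beta_k over
// t in [0,1]; control points are advected by the same field; momenta are held
// constant along the flow. Returns final positions and the full trajectories
// (needed by the adjoint pass).
// [[Rcpp::export]]
List cpp_flow(NumericMatrix x0, NumericMatrix c0, NumericMatrix beta,
              double lambda, int steps) {
  int N = x0.nrow(), K = c0.nrow();
  double h = 1.0 / steps, il2 = 1.0 / (lambda * lambda);
  NumericVector xs(Dimension(N, 3, steps + 1));
  NumericVector cs(Dimension(K, 3, steps + 1));
  std::vector<double> x(3 * N), c(3 * K);
  for (int a = 0; a < N; ++a)
    for (int q = 0; q < 3; ++q) {
      x[3 * a + q] = x0(a, q);
      xs[a + N * q] = x0(a, q);
    }
  for (int k = 0; k < K; ++k)
    for (int q = 0; q < 3; ++q) {
      c[3 * k + q] = c0(k, q);
      cs[k + K * q] = c0(k, q);
    }
  std::vector<double> vx(3 * N), vc(3 * K);
  for (int s = 0; s < steps; ++s) {
    std::fill(vx.begin(), vx.end(), 0.0);
    std::fill(vc.begin(), vc.end(), 0.0);
    for (int a = 0; a < N; ++a) {
      for (int k = 0; k < K; ++k) {
        double d0 = x[3 * a] - c[3 * k], d1 = x[3 * a + 1] - c[3 * k + 1],
               d2 = x[3 * a + 2] - c[3 * k + 2];
        double kv = std::exp(-(d0 * d0 + d1 * d1 + d2 * d2) * il2);
        for (int q = 0; q < 3; ++q) vx[3 * a + q] += kv * beta(k, q);
      }
    }
    for (int l = 0; l < K; ++l) {
      for (int k = 0; k < K; ++k) {
        double d0 = c[3 * l] - c[3 * k], d1 = c[3 * l + 1] - c[3 * k + 1],
               d2 = c[3 * l + 2] - c[3 * k + 2];
        double kv = std::exp(-(d0 * d0 + d1 * d1 + d2 * d2) * il2);
        for (int q = 0; q < 3; ++q) vc[3 * l + q] += kv * beta(k, q);
      }
    }
    for (int a = 0; a < N; ++a)
      for (int q = 0; q < 3; ++q) {
        x[3 * a + q] += h * vx[3 * a + q];
        xs[a + N * q + N * 3 * (s + 1)] = x[3 * a + q];
      }
    for (int k = 0; k < K; ++k)
      for (int q = 0; q < 3; ++q) {
        c[3 * k + q] += h * vc[3 * k + q];
        cs[k + K * q + K * 3 * (s + 1)] = c[3 * k + q];
      }
    if (!std::isfinite(x[0]))
      stop("non-finite intermediate state in flow integration");
  }
  NumericMatrix xf(N, 3), cf(K, 3);
  for (int a = 0; a < N; ++a)
    for (int q = 0; q < 3; ++q) xf(a, q) = x[3 * a + q];
  for (int k = 0; k < K; ++k)
    for (int q = 0; q < 3; ++q) cf(k, q) = c[3 * k + q];
  return List::create(_["x"] = xf, _["c"] = cf, _["xs"] = xs, _["cs"] = cs);
}

// Adjoint (reverse-mode) pass: given d(loss)/d(final vertices), accumulate
// d(loss)/d(momenta) and d(loss)/d(initial vertices) through the Euler steps.
// [[Rcpp::export]]
List cpp_flow_vjp(NumericVector xs, NumericVector cs, NumericMatrix beta,
                  double lambda, int steps, NumericMatrix bar_x_final) {
  IntegerVector dx = xs.attr("dim");
  IntegerVector dc = cs.attr("dim");
  int N = dx[0], K = dc[0];
  double h = 1.0 / steps, il2 = 1.0 / (lambda * lambda);
  std::vector<double> bx(3 * N), bc(3 * K, 0.0);
  for (int a = 0; a < N; ++a)
    for (int q = 0; q < 3; ++q) bx[3 * a + q] = bar_x_final(a, q);
  NumericMatrix dbeta(K, 3);
  std::vector<double> nbx(3 * N), nbc(3 * K);
  for (int s = steps - 1; s >= 0; --s) {
    const double *X = &xs[N * 3 * s];
    const double *C = &cs[K * 3 * s];
    // X[a + N*q], C[k + K*q]
    for (int a = 0; a < N; ++a)
      for (int q = 0; q < 3; ++q) nbx[3 * a + q] = bx[3 * a + q];
    for (int k = 0; k < K; ++k)
      for (int q = 0; q < 3; ++q) nbc[3 * k + q] = bc[3 * k + q];
    for (int a = 0; a < N; ++a) {
      double xa[3] = {X[a], X[a + N], X[a + 2 * N]};
      double ba[3] = {bx[3 * a], bx[3 * a + 1], bx[3 * a + 2]};
      for (int k = 0; k < K; ++k) {
        double d[3] = {xa[0] - C[k], xa[1] - C[k + K], xa[2] - C[k + 2 * K]};
        double kv = std::exp(-(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]) * il2);
        double bdot = beta(k, 0) * ba[0] + beta(k, 1) * ba[1] +
                      beta(k, 2) * ba[2];
        double w = h * kv * (-2.0 * il2) * bdot;
        for (int q = 0; q < 3; ++q) {
          dbeta(k, q) += h * kv * ba[q];
          nbx[3 * a + q] += w * d[q];
          nbc[3 * k + q] -= w * d[q];
        }
      }
    }
    for (int l = 0; l < K; ++l) {
      double cl[3] = {C[l], C[l + K], C[l + 2 * K]};
      double bl[3] = {bc[3 * l], bc[3 * l + 1], bc[3 * l + 2]};
      for (int k = 0; k < K; ++k) {
        double d[3] = {cl[0] - C[k], cl[1] - C[k + K], cl[2] - C[k + 2 * K]};
        double kv = std::exp(-(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]) * il2);
        double bdot = beta(k, 0) * bl[0] + beta(k, 1) * bl[1] +
                      beta(k, 2) * bl[2];
        double w = h * kv * (-2.0 * il2) * bdot;
        for (int q = 0; q < 3; ++q) {
          dbeta(k, q) += h * kv * bl[q];
          nbc[3 * l + q] += w * d[q];
          nbc[3 * k + q] -= w * d[q];
        }
      }
    }
    bx.swap(nbx);
    bc.swap(nbc);
  }
  NumericMatrix dx0(N, 3);
  for (int a = 0; a < N; ++a)
    for (int q = 0; q < 3; ++q) dx0(a, q) = bx[3 * a + q];
  return List::create(_["dbeta"] = dbeta, _["dx0"] = dx0);
}
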