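#include <Rcpp.h>
#include <R_ext/Lapack.h>
using namespace Rcpp;

// Banded LU solve (LAPACK dgbsv) for A x = b with A given as 0-based
// triplets (ti, tj, tx). All entries must satisfy |i - j| <= kd; the
// state-space linearization guarantees kd = 16*M for the CME generator.
// [[Rcpp::export]]
NumericVector cpp_band_solve(IntegerVector ti, IntegerVector tj, NumericVector tx,
                             int n, int kd, NumericVector b) {
  int kl = kd, ku = kd;
  int ldab = 2 * kl + ku + 1;
  std::vector<double> ab((size_t)ldab * n, 0.0);
  for (R_xlen_t k = 0; k < ti.size(); ++k) {
    int i = ti[k], j = tj[k];
    if (i < 0 || j < 0 || i >= n || j >= n)
      stop("triplet index out of range");
    if (std::abs(i - j) > kd)
      stop("entry outside declared bandwidth");
    ab[(size_t)j * ldab + (kl + ku + i - j)] += tx[k];
  }
  std::vector<int> ipiv(n);
  NumericVector x = clone(b);
  int info = 0, nrhs = 1;
  F77_CALL(dgbsv)(&n, &kl, &ku, &nrhs, ab.data(), &ldab, ipiv.data(),
                  x.begin(), &n, &info);
  if (info != 0)
    stop("banded LU solve failed (LAPACK dgbsv info = %d); the chain may be reducible", info);
  return x;
}

// Direct-method stochastic simulation of the two-gene network, returning
// the time-weighted occupancy over the full enumerated state space.
// gx, gy: length-4 synthesis rates per promoter state (00, self, other, both).
// init: (nx, ny, sx, sy). Occupancy is accumulated after t > burn_frac * t_end.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cpp_ssa_occupancy(int M, NumericVector gx, NumericVector gy,
                                double k, double ha, double fa, double hr, double fr,
                                double t_end, double burn_frac, IntegerVector init) {
  const int N = 16 * M * M;
  NumericVector occ(N);
  int nx = init[0], ny = init[1], sx = init[2], sy = init[3];
  if (t_end <= 0.0) {
    occ[sy + 4 * sx + 16 * (ny + M * nx)] = 1.0;
    return occ;
  }
  const double t_burn = burn_frac * t_end;
  double t = 0.0, total_w = 0.0;
  RNGScope scope;
  double a[20];
  while (t < t_end) {
    // synthesis (reflecting at M-1) and degradation
    a[0] = (nx < M - 1) ? gx[sx] : 0.0;
    a[1] = (ny < M - 1) ? gy[sy] : 0.0;
    a[2] = k * nx;
    a[3] = k * ny;
    // promoter X: self regulator is x mRNA, cross regulator is y mRNA
    double bsx = ha * nx * (double)nx / 2.0, bcx = hr * ny * (double)ny / 2.0;
    a[4] = (sx == 0) ? bsx : 0.0;  // 00 -> self
    a[5] = (sx == 1) ? fa : 0.0;   // self -> 00
    a[6] = (sx == 0) ? bcx : 0.0;  // 00 -> other
    a[7] = (sx == 2) ? fr : 0.0;   // other -> 00
    a[8] = (sx == 1) ? bcx : 0.0;  // self -> both
    a[9] = (sx == 3) ? fr : 0.0;   // both -> self
    a[10] = (sx == 2) ? bsx : 0.0; // other -> both
    a[11] = (sx == 3) ? fa : 0.0;  // both -> other
    // promoter Y (mirror image)
    double bsy = ha * ny * (double)ny / 2.0, bcy = hr * nx * (double)nx / 2.0;
    a[12] = (sy == 0) ? bsy : 0.0;
    a[13] = (sy == 1) ? fa : 0.0;
    a[14] = (sy == 0) ? bcy : 0.0;
    a[15] = (sy == 2) ? fr : 0.0;
    a[16] = (sy == 1) ? bcy : 0.0;
    a[17] = (sy == 3) ? fr : 0.0;
    a[18] = (sy == 2) ? bsy : 0.0;
    a[19] = (sy == 3) ? fa : 0.0;
    double a0 = 0.0;
    for (int i = 0; i < 20; ++i) a0 += a[i];
    if (a0 <= 0.0) { // absorbing (cannot occur when rates are positive)
      double dt = t_end - t, t1 = std::max(t, t_burn);
      if (t_end > t1) { occ[sy + 4 * sx + 16 * (ny + M * nx)] += t_end - t1; total_w += t_end - t1; }
      t += dt;
      break;
    }
    double dt = -std::log(unif_rand()) / a0;
    double t_next = t + dt;
    double lo = std::max(t, t_burn), hi = std::min(t_next, t_end);
    if (hi > lo) {
      occ[sy + 4 * sx + 16 * (ny + M * nx)] += hi - lo;
      total_w += hi - lo;
    }
    if (t_next >= t_end) break;
    t = t_next;
    double r = unif_rand() * a0, cum = 0.0;
    int ch = 19;
    for (int i = 0; i < 20; ++i) { cum += a[i]; if (r < cum) { ch = i; break; } }
    switch (ch) {
      case 0: ++nx; break;
      case 1: ++ny; break;
      case 2: --nx; break;
      case 3: --ny; break;
      case 4: sx = 1; break;
      case 5: sx = 0; break;
      case 6: sx = 2; break;
      case 7: sx = 0; break;
      case 8: sx = 3; break;
      case 9: sx = 1; break;
      case 10: sx = 3; break;
      case 11: sx = 2; break;
      case 12: sy = 1; break;
      case 13: sy = 0; break;
      case 14: sy = 2; break;
      case 15: sy = 0; break;
      case 16: sy = 3; break;
      case 17: sy = 1; break;
      case 18: sy = 3; break;
      case 19: sy = 2; break;
    }
  }
  if (total_w > 0.0) for (int i = 0; i < N; ++i) occ[i] /= total_w;
  return occ;
}
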