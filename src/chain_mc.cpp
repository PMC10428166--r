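#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Metropolis Monte Carlo for a one-bead-per-residue chain with fixed bond
// length. Moves: pivot (rigid rotation of a chain tail about a random bead)
// and crankshaft (rotation of an interior segment about the axis through its
// anchors). Both preserve bond lengths exactly, so only nonbonded pair terms
// between the moved and static parts and the bending terms at the move
// boundaries enter the Metropolis ratio.
//
// Energy (kT units, distances nm):
//   bend:        k_i (1 - cos phi_i) at each interior vertex
//   hard core:   infinite for nonbonded pairs (|i-j| >= 2) closer than diam
//   Debye-Hueckel: lB q_i q_j exp(-d/lambda)/d, cutoff 4 lambda
//   square well: -eps[g_i][g_j] for d < well_cut (residue-group attraction,
//                the cation-pi cell lives in the same matrix)

struct ChainParams {
  double b, diam2, lB, lambda, elec_cut2, well_cut2;
  std::vector<double> kbend, q;
  std::vector<int> grp;
  std::vector<double> eps;  // ngrp x ngrp, row-major
  int ngrp;
  bool has_elec, has_well;
};

static inline double pair_energy(const ChainParams &P,
                                 double dx, double dy, double dz,
                                 int i, int j) {
  double d2 = dx * dx + dy * dy + dz * dz;
  if (d2 < P.diam2) return R_PosInf;
  double e = 0.0;
  if (P.has_well && d2 < P.well_cut2)
    e -= P.eps[P.grp[i] * P.ngrp + P.grp[j]];
  if (P.has_elec && d2 < P.elec_cut2) {
    double qq = P.q[i] * P.q[j];
    if (qq != 0.0) {
      double d = std::sqrt(d2);
      e += P.lB * qq * std::exp(-d / P.lambda) / d;
    }
  }
  return e;
}

static inline double bend_energy_at(const std::vector<double> &x,
                                    const std::vector<double> &y,
                                    const std::vector<double> &z,
                                    const ChainParams &P, int v, int N) {
  if (v <= 0 || v >= N - 1) return 0.0;
  double k = P.kbend[v];
  if (k == 0.0) return 0.0;
  double ux = x[v] - x[v - 1], uy = y[v] - y[v - 1], uz = z[v] - z[v - 1];
  double vx = x[v + 1] - x[v], vy = y[v + 1] - y[v], vz = z[v + 1] - z[v];
  double c = (ux * vx + uy * vy + uz * vz) /
             (std::sqrt(ux * ux + uy * uy + uz * uz) *
              std::sqrt(vx * vx + vy * vy + vz * vz));
  return k * (1.0 - c);
}

// energy of moved beads [m0, m1] against static beads, skipping bonded pairs
static double cross_energy(const std::vector<double> &x,
                           const std::vector<double> &y,
                           const std::vector<double> &z,
                           const ChainParams &P, int m0, int m1, int N) {
  double e = 0.0;
  for (int i = m0; i <= m1; ++i) {
    for (int j = 0; j < N; ++j) {
      if (j >= m0 && j <= m1) continue;
      if (std::abs(i - j) < 2) continue;
      e += pair_energy(P, x[i] - x[j], y[i] - y[j], z[i] - z[j], i, j);
      if (!R_finite(e)) return R_PosInf;
    }
  }
  return e;
}

static inline void rotate_about(double axx, double axy, double axz,
                                double px, double py, double pz,
                                double angle,
                                double &X, double &Y, double &Z) {
  // Rodrigues rotation of (X,Y,Z) about unit axis (axx,axy,axz) through point p
  double c = std::cos(angle), s = std::sin(angle);
  double vx = X - px, vy = Y - py, vz = Z - pz;
  double dot = axx * vx + axy * vy + axz * vz;
  double cx = axy * vz - axz * vy;
  double cy = axz * vx - axx * vz;
  double cz = axx * vy - axy * vx;
  X = px + vx * c + cx * s + axx * dot * (1 - c);
  Y = py + vy * c + cy * s + axy * dot * (1 - c);
  Z = pz + vz * c + cz * s + axz * dot * (1 - c);
}

// [[Rcpp::export(name = ".sample_chain_cpp")]]
List sample_chain_cpp(int N, int n_frames, int stride, int burnin,
                      double b, double diam,
                      NumericVector kbend, NumericVector q,
                      double lB, double lambdaD,
                      NumericMatrix eps, IntegerVector grp,
                      double well_cut) {
  ChainParams P;
  P.b = b;
  P.diam2 = diam * diam;
  P.lB = lB;
  P.lambda = lambdaD;
  P.elec_cut2 = 16.0 * lambdaD * lambdaD;
  P.well_cut2 = well_cut * well_cut;
  P.kbend.assign(kbend.begin(), kbend.end());
  P.q.assign(q.begin(), q.end());
  P.grp.assign(grp.begin(), grp.end());
  P.ngrp = eps.nrow();
  P.eps.assign(eps.begin(), eps.end());
  P.has_elec = false;
  for (double qi : P.q) if (qi != 0.0) { P.has_elec = true; break; }
  P.has_well = false;
  for (double e : P.eps) if (e != 0.0) { P.has_well = true; break; }

  // start from a straight rod along x (no overlaps, zero bend energy)
  std::vector<double> x(N), y(N, 0.0), z(N, 0.0);
  for (int i = 0; i < N; ++i) x[i] = i * b;

  NumericVector frames((R_xlen_t)N * 3 * n_frames);
  long accepted = 0, attempted = 0;
  std::vector<double> nx(N), ny(N), nz(N);
  long total_moves = (long)burnin + (long)stride * n_frames;
  int frame = 0;
  long next_store = burnin;

  for (long mv = 1; mv <= total_moves; ++mv) {
    ++attempted;
    bool do_pivot = (N < 5) || (unif_rand() < 0.7);
    int m0, m1;               // moved range (inclusive)
    int bv1 = -1, bv2 = -1;   // vertices whose bend term changes
    double ax, ay, az, px, py, pz, angle;

    if (do_pivot) {
      int p = 1 + (int)(unif_rand() * (N - 2));  // pivot bead 1..N-2
      bool tail = unif_rand() < 0.5;
      if (tail) { m0 = p + 1; m1 = N - 1; } else { m0 = 0; m1 = p - 1; }
      bv1 = p;
      // random axis uniform on the sphere
      double u = 2.0 * unif_rand() - 1.0, phi = 2.0 * M_PI * unif_rand();
      double s = std::sqrt(1.0 - u * u);
      ax = s * std::cos(phi); ay = s * std::sin(phi); az = u;
      px = x[p]; py = y[p]; pz = z[p];
      angle = 2.0 * M_PI * unif_rand();
    } else {
      int span = 2 + (int)(unif_rand() * std::min(8, N - 2));
      int i = (int)(unif_rand() * (N - span));
      int j = i + span;
      m0 = i + 1; m1 = j - 1;
      bv1 = i; bv2 = j;
      double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (nrm < 1e-12) continue;
      ax = dx / nrm; ay = dy / nrm; az = dz / nrm;
      px = x[i]; py = y[i]; pz = z[i];
      angle = 2.0 * M_PI * unif_rand();
    }

    double e_old = cross_energy(x, y, z, P, m0, m1, N) +
                   bend_energy_at(x, y, z, P, bv1, N) +
                   (bv2 >= 0 ? bend_energy_at(x, y, z, P, bv2, N) : 0.0);

    nx = x; ny = y; nz = z;
    for (int i = m0; i <= m1; ++i)
      rotate_about(ax, ay, az, px, py, pz, angle, nx[i], ny[i], nz[i]);

    double e_new = cross_energy(nx, ny, nz, P, m0, m1, N);
    if (R_finite(e_new)) {
      e_new += bend_energy_at(nx, ny, nz, P, bv1, N) +
               (bv2 >= 0 ? bend_energy_at(nx, ny, nz, P, bv2, N) : 0.0);
      double dE = e_new - e_old;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
        x.swap(nx); y.swap(ny); z.swap(nz);
        ++accepted;
      }
    }

    if (mv == next_store && frame < n_frames) {
      double cx = 0, cy = 0, cz = 0;
      for (int i = 0; i < N; ++i) { cx += x[i]; cy += y[i]; cz += z[i]; }
      cx /= N; cy /= N; cz /= N;
      R_xlen_t off = (R_xlen_t)frame * N * 3;
      for (int i = 0; i < N; ++i) {
        frames[off + i] = x[i] - cx;
        frames[off + N + i] = y[i] - cy;
        frames[off + 2 * N + i] = z[i] - cz;
      }
      ++frame;
      next_store += stride;
    }
  }

  frames.attr("dim") = IntegerVector::create(N, 3, n_frames);
  return List::create(_["frames"] = frames,
                      _["acceptance"] = (double)accepted / (double)attempted);
}

// Fraction of frames in which each residue pair sits within `cutoff`,
// with the near-diagonal band |i-j| <= exclusion zeroed.
// [[Rcpp::export(name = ".contact_map_cpp")]]
NumericMatrix contact_map_cpp(NumericVector frames, double cutoff,
                              int exclusion) {
  IntegerVector dim = frames.attr("dim");
  int N = dim[0], F = dim[2];
  NumericMatrix out(N, N);
  double c2 = cutoff * cutoff;
  for (int f = 0; f < F; ++f) {
    R_xlen_t off = (R_xlen_t)f * N * 3;
    for (int i = 0; i < N; ++i) {
      double xi = frames[off + i], yi = frames[off + N + i],
             zi = frames[off + 2 * N + i];
      for (int j = i + exclusion + 1; j < N; ++j) {
        double dx = xi - frames[off + j];
        double dy = yi - frames[off + N + j];
        double dz = zi - frames[off + 2 * N + j];
        if (dx * dx + dy * dy + dz * dz <= c2) out(i, j) += 1.0;
      }
    }
  }
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      out(i, j) /= F;
      out(j, i) = out(i, j);
    }
  return out;
}
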