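// Core simulation kernels: pair energies/forces for the coarse-grained
// models (Ashbaugh-Hatch / Wang-Frenkel hydrophobic terms, unified
// screened-Coulomb term pref*exp(-kappa r)/r, optional cation-pi LJ),
// harmonic bonds, Verlet-list BAOAB Langevin dynamics with virial stress
// sampling, and intermolecular contact accumulation.
//
// Internal units: nm, kJ/mol, ps, K, e, g/mol (kB = 8.3144621e-3).

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static const double KB = 8.3144621e-3;

struct PairTables {
  int n;            // number of residue types
  int hscheme;      // 1 = Ashbaugh-Hatch, 2 = Wang-Frenkel
  const double *heps, *hsig, *hshape, *halpha, *hcut, *epref, *cpeps, *cpsig;
  double kappa, ecut, bond_k, bond_r0, maxcut;
};

static PairTables unpack(const List &par) {
  PairTables P;
  P.hscheme = as<int>(par["hscheme"]);
  NumericMatrix heps = par["heps"];
  P.n = heps.nrow();
  P.heps = REAL(par["heps"]);
  P.hsig = REAL(par["hsig"]);
  P.hshape = REAL(par["hshape"]);
  P.halpha = REAL(par["halpha"]);
  P.hcut = REAL(par["hcut"]);
  P.epref = REAL(par["epref"]);
  P.cpeps = REAL(par["cpeps"]);
  P.cpsig = REAL(par["cpsig"]);
  P.kappa = as<double>(par["kappa"]);
  P.ecut = as<double>(par["ecut"]);
  P.bond_k = as<double>(par["bond_k"]);
  P.bond_r0 = as<double>(par["bond_r0"]);
  P.maxcut = as<double>(par["maxcut"]);
  return P;
}

// energy and radial derivative dE/dr for the nonbonded pair (a, b) at r
static inline void pair_ef(const PairTables &P, int a, int b, double r,
                           double &E, double &dEdr, bool with_catpi = true) {
  const int k = a + P.n * b;
  double e = 0.0, d = 0.0;
  const double hcut = P.hcut[k];
  if (r < hcut) {
    const double sig = P.hsig[k], eps = P.heps[k];
    if (P.hscheme == 1) {
      const double lam = P.hshape[k];
      const double sr2 = sig * sig / (r * r);
      const double sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
      const double lj = 4.0 * eps * (sr12 - sr6);
      const double dlj = 4.0 * eps * (-12.0 * sr12 + 6.0 * sr6) / r;
      if (r < 1.1224620483093730 * sig) {
        e += lj + (1.0 - lam) * eps;
        d += dlj;
      } else {
        e += lam * lj;
        d += lam * dlj;
      }
    } else {
      const double nu = P.hshape[k], alpha = P.halpha[k];
      const double s = sig * sig / (r * r);       // (sigma/r)^2, mu = 1
      const double c = hcut * hcut / (r * r);     // (rc/r)^2
      const double cm = c - 1.0;
      const double pw = std::pow(cm, 2.0 * nu - 1.0);
      e += eps * alpha * (s - 1.0) * pw * cm;
      d += eps * alpha * ((-2.0 * s / r) * pw * cm +
                          (s - 1.0) * 2.0 * nu * pw * (-2.0 * c / r));
    }
  }
  if (r < P.ecut) {
    const double p = P.epref[k];
    if (p != 0.0) {
      const double ex = p * std::exp(-P.kappa * r) / r;
      e += ex;
      d += -ex * (P.kappa + 1.0 / r);
    }
  }
  if (with_catpi) {
    const double cpe = P.cpeps[k];
    if (cpe != 0.0) {
      const double cs = P.cpsig[k];
      if (r < 3.0 * cs) {
        const double sr2 = cs * cs / (r * r);
        const double sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
        e += 4.0 * cpe * (sr12 - sr6);
        d += 4.0 * cpe * (-12.0 * sr12 + 6.0 * sr6) / r;
      }
    }
  }
  E = e;
  dEdr = d;
}

static inline double mimg(double d, double L) {
  return d - L * std::round(d / L);
}

typedef std::unordered_set<long long> PairSet;

static PairSet bonded_set(const IntegerMatrix &bonds, int N) {
  PairSet s;
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    if (i > j) std::swap(i, j);
    s.insert((long long)i * N + j);
  }
  return s;
}

// brute-force O(N^2) neighbour list within rlist (bonded pairs excluded)
static void build_nlist(const std::vector<double> &x,
                        const std::vector<double> &y,
                        const std::vector<double> &z, const double *L, int N,
                        double rlist, const PairSet &excl,
                        std::vector<int> &plist) {
  plist.clear();
  const double r2 = rlist * rlist;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      const double dx = mimg(x[i] - x[j], L[0]);
      const double dy = mimg(y[i] - y[j], L[1]);
      const double dz = mimg(z[i] - z[j], L[2]);
      if (dx * dx + dy * dy + dz * dz < r2) {
        if (excl.count((long long)i * N + j)) continue;
        plist.push_back(i);
        plist.push_back(j);
      }
    }
  }
}

struct ForceResult {
  double e_pair, e_bond;
  double virial[9];
};

// forces from the neighbour list + bonds; virial accumulates f_i (x) r_ij
static ForceResult compute_forces(const PairTables &P,
                                  const std::vector<double> &x,
                                  const std::vector<double> &y,
                                  const std::vector<double> &z,
                                  const double *L, const IntegerVector &type,
                                  const IntegerMatrix &bonds,
                                  const std::vector<int> &plist,
                                  std::vector<double> &fx,
                                  std::vector<double> &fy,
                                  std::vector<double> &fz) {
  const int N = (int)x.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  ForceResult res;
  res.e_pair = 0.0;
  res.e_bond = 0.0;
  for (int a = 0; a < 9; ++a) res.virial[a] = 0.0;
  const double cut2 = P.maxcut * P.maxcut;
  for (size_t p = 0; p < plist.size(); p += 2) {
    const int i = plist[p], j = plist[p + 1];
    const double dx = mimg(x[i] - x[j], L[0]);
    const double dy = mimg(y[i] - y[j], L[1]);
    const double dz = mimg(z[i] - z[j], L[2]);
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= cut2) continue;
    const double r = std::sqrt(r2);
    double e, dEdr;
    pair_ef(P, type[i], type[j], r, e, dEdr);
    res.e_pair += e;
    const double fr = -dEdr / r;  // f_i = fr * dr
    const double fxi = fr * dx, fyi = fr * dy, fzi = fr * dz;
    fx[i] += fxi; fy[i] += fyi; fz[i] += fzi;
    fx[j] -= fxi; fy[j] -= fyi; fz[j] -= fzi;
    res.virial[0] += fxi * dx; res.virial[4] += fyi * dy;
    res.virial[8] += fzi * dz;
    res.virial[1] += fxi * dy; res.virial[2] += fxi * dz;
    res.virial[5] += fyi * dz;
  }
  for (int b = 0; b < bonds.nrow(); ++b) {
    const int i = bonds(b, 0), j = bonds(b, 1);
    const double dx = mimg(x[i] - x[j], L[0]);
    const double dy = mimg(y[i] - y[j], L[1]);
    const double dz = mimg(z[i] - z[j], L[2]);
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    const double dr = r - P.bond_r0;
    res.e_bond += P.bond_k * dr * dr;
    const double fr = -2.0 * P.bond_k * dr / r;
    const double fxi = fr * dx, fyi = fr * dy, fzi = fr * dz;
    fx[i] += fxi; fy[i] += fyi; fz[i] += fzi;
    fx[j] -= fxi; fy[j] -= fyi; fz[j] -= fzi;
    res.virial[0] += fxi * dx; res.virial[4] += fyi * dy;
    res.virial[8] += fzi * dz;
    res.virial[1] += fxi * dy; res.virial[2] += fxi * dz;
    res.virial[5] += fyi * dz;
  }
  res.virial[3] = res.virial[1];
  res.virial[6] = res.virial[2];
  res.virial[7] = res.virial[5];
  return res;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, NumericVector box,
                       IntegerVector type, IntegerMatrix bonds, List par) {
  const PairTables P = unpack(par);
  const int N = pos.nrow();
  std::vector<double> x(N), y(N), z(N), fx(N), fy(N), fz(N);
  for (int i = 0; i < N; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
  }
  const double L[3] = {box[0], box[1], box[2]};
  PairSet excl = bonded_set(bonds, N);
  std::vector<int> plist;
  build_nlist(x, y, z, L, N, P.maxcut, excl, plist);
  ForceResult res =
      compute_forces(P, x, y, z, L, type, bonds, plist, fx, fy, fz);
  NumericMatrix F(N, 3), W(3, 3);
  for (int i = 0; i < N; ++i) {
    F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i];
  }
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) W(a, b) = res.virial[3 * a + b];
  return List::create(_["energy"] = res.e_pair + res.e_bond,
                      _["e_pair"] = res.e_pair, _["e_bond"] = res.e_bond,
                      _["forces"] = F, _["virial"] = W);
}

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos, NumericMatrix vel,
                      NumericVector box, IntegerVector type,
                      NumericVector mass, IntegerMatrix bonds, List par,
                      double dt, double gamma, double Tbath, int nsteps,
                      int seed, int sample_every, int stress_every,
                      double skin, bool thermostat, double max_disp) {
  const PairTables P = unpack(par);
  const int N = pos.nrow();
  std::vector<double> x(N), y(N), z(N), vx(N), vy(N), vz(N), fx(N), fy(N),
      fz(N), x0(N), y0(N), z0(N), ux(N), uy(N), uz(N);
  for (int i = 0; i < N; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
    ux[i] = x[i]; uy[i] = y[i]; uz[i] = z[i];  // unwrapped, for NL criterion
  }
  const double L[3] = {box[0], box[1], box[2]};
  const double V = L[0] * L[1] * L[2];
  PairSet excl = bonded_set(bonds, N);
  std::vector<int> plist;
  const double rlist = P.maxcut + skin;
  build_nlist(x, y, z, L, N, rlist, excl, plist);
  x0 = ux; y0 = uy; z0 = uz;

  std::mt19937_64 rng((unsigned long long)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  const double c1 = thermostat ? std::exp(-gamma * dt) : 1.0;
  const double c2 = thermostat ? std::sqrt(1.0 - c1 * c1) : 0.0;
  std::vector<double> sqkTm(N);
  for (int i = 0; i < N; ++i) sqkTm[i] = std::sqrt(KB * Tbath / mass[i]);

  ForceResult res =
      compute_forces(P, x, y, z, L, type, bonds, plist, fx, fy, fz);

  const int nframes = sample_every > 0 ? nsteps / sample_every : 0;
  const int nstress = stress_every > 0 ? nsteps / stress_every : 0;
  NumericVector frames((R_xlen_t)nframes * N * 3);
  NumericVector ftimes(nframes);
  NumericMatrix stress(nstress, 7);   // t, xy, xz, yz, xx, yy, zz
  NumericMatrix elog(nstress > 0 ? nstress : nframes, 4);  // t, pe, ke, T
  int iframe = 0, istress = 0, ielog = 0;

  auto wrap = [&](int i) {
    x[i] -= L[0] * std::floor(x[i] / L[0]);
    y[i] -= L[1] * std::floor(y[i] / L[1]);
    z[i] -= L[2] * std::floor(z[i] / L[2]);
  };

  // displacement cap (relaxation runs only): scale a bead's velocity so a
  // half drift never exceeds max_disp/2
  const double dlim = max_disp > 0 ? 0.5 * max_disp : 0.0;
  auto cap = [&](int i) {
    if (dlim <= 0) return;
    const double d = 0.5 * dt *
        std::sqrt(vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    if (d > dlim) {
      const double f = dlim / d;
      vx[i] *= f; vy[i] *= f; vz[i] *= f;
    }
  };

  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < N; ++i) {
      const double h = 0.5 * dt / mass[i];
      vx[i] += h * fx[i]; vy[i] += h * fy[i]; vz[i] += h * fz[i];
      cap(i);
      ux[i] += 0.5 * dt * vx[i]; uy[i] += 0.5 * dt * vy[i];
      uz[i] += 0.5 * dt * vz[i];
      if (thermostat) {
        vx[i] = c1 * vx[i] + c2 * sqkTm[i] * gauss(rng);
        vy[i] = c1 * vy[i] + c2 * sqkTm[i] * gauss(rng);
        vz[i] = c1 * vz[i] + c2 * sqkTm[i] * gauss(rng);
      }
      cap(i);
      ux[i] += 0.5 * dt * vx[i]; uy[i] += 0.5 * dt * vy[i];
      uz[i] += 0.5 * dt * vz[i];
      x[i] = ux[i]; y[i] = uy[i]; z[i] = uz[i];
      wrap(i);
    }
    // rebuild neighbour list when any displacement exceeds half the skin
    double maxd2 = 0.0;
    for (int i = 0; i < N; ++i) {
      const double dx = ux[i] - x0[i], dy = uy[i] - y0[i],
                   dz = uz[i] - z0[i];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > maxd2) maxd2 = d2;
    }
    if (maxd2 > 0.25 * skin * skin) {
      build_nlist(x, y, z, L, N, rlist, excl, plist);
      x0 = ux; y0 = uy; z0 = uz;
    }
    res = compute_forces(P, x, y, z, L, type, bonds, plist, fx, fy, fz);
    if (!std::isfinite(res.e_pair + res.e_bond)) {
      stop("non-finite energy/forces at step %d", step);
    }
    for (int i = 0; i < N; ++i) {
      const double h = 0.5 * dt / mass[i];
      vx[i] += h * fx[i]; vy[i] += h * fy[i]; vz[i] += h * fz[i];
    }

    if (stress_every > 0 && step % stress_every == 0) {
      double K[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
      double ke = 0.0;
      for (int i = 0; i < N; ++i) {
        const double m = mass[i];
        K[0] += m * vx[i] * vx[i]; K[4] += m * vy[i] * vy[i];
        K[8] += m * vz[i] * vz[i];
        K[1] += m * vx[i] * vy[i]; K[2] += m * vx[i] * vz[i];
        K[5] += m * vy[i] * vz[i];
      }
      ke = 0.5 * (K[0] + K[4] + K[8]);
      stress(istress, 0) = step * dt;
      stress(istress, 1) = (K[1] + res.virial[1]) / V;
      stress(istress, 2) = (K[2] + res.virial[2]) / V;
      stress(istress, 3) = (K[5] + res.virial[5]) / V;
      stress(istress, 4) = (K[0] + res.virial[0]) / V;
      stress(istress, 5) = (K[4] + res.virial[4]) / V;
      stress(istress, 6) = (K[8] + res.virial[8]) / V;
      elog(ielog, 0) = step * dt;
      elog(ielog, 1) = res.e_pair + res.e_bond;
      elog(ielog, 2) = ke;
      elog(ielog, 3) = 2.0 * ke / (3.0 * N * KB);
      ++istress;
      ++ielog;
    }
    if (sample_every > 0 && step % sample_every == 0) {
      const R_xlen_t off = (R_xlen_t)iframe * N * 3;
      for (int i = 0; i < N; ++i) {
        frames[off + i] = x[i];
        frames[off + N + i] = y[i];
        frames[off + 2 * N + i] = z[i];
      }
      ftimes[iframe] = step * dt;
      ++iframe;
    }
  }

  NumericMatrix posOut(N, 3), velOut(N, 3);
  for (int i = 0; i < N; ++i) {
    posOut(i, 0) = x[i]; posOut(i, 1) = y[i]; posOut(i, 2) = z[i];
    velOut(i, 0) = vx[i]; velOut(i, 1) = vy[i]; velOut(i, 2) = vz[i];
  }
  return List::create(_["frames"] = frames, _["times"] = ftimes,
                      _["stress"] = stress, _["energies"] = elog,
                      _["positions"] = posOut, _["velocities"] = velOut,
                      _["n_frames"] = iframe);
}

// kinetic + pair-virial stress of a single configuration
// [[Rcpp::export]]
NumericMatrix cpp_virial_stress(NumericMatrix pos, NumericMatrix vel,
                                NumericVector box, IntegerVector type,
                                NumericVector mass, IntegerMatrix bonds,
                                List par) {
  List ef = cpp_energy_forces(pos, box, type, bonds, par);
  NumericMatrix W = ef["virial"];
  const int N = pos.nrow();
  const double V = box[0] * box[1] * box[2];
  double K[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
  for (int i = 0; i < N; ++i) {
    const double m = mass[i];
    K[0] += m * vel(i, 0) * vel(i, 0); K[4] += m * vel(i, 1) * vel(i, 1);
    K[8] += m * vel(i, 2) * vel(i, 2);
    K[1] += m * vel(i, 0) * vel(i, 1); K[2] += m * vel(i, 0) * vel(i, 2);
    K[5] += m * vel(i, 1) * vel(i, 2);
  }
  K[3] = K[1]; K[6] = K[2]; K[7] = K[5];
  NumericMatrix S(3, 3);
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) S(a, b) = (K[3 * a + b] + W(a, b)) / V;
  return S;
}

// intermolecular contact counts (and optional pair-energy sums) between
// beads on different chains, cutoff = factor * sigma_ij
// [[Rcpp::export]]
List cpp_contact_maps(NumericMatrix pos, NumericVector box,
                      IntegerVector chain, IntegerVector type,
                      IntegerVector seqpos, int L_seq, List par,
                      double factor, bool with_energy) {
  const PairTables P = unpack(par);
  const int N = pos.nrow();
  const double L[3] = {box[0], box[1], box[2]};
  NumericMatrix fmap(L_seq, L_seq), emap(L_seq, L_seq);
  double maxsig = 0.0;
  for (int k = 0; k < P.n * P.n; ++k)
    if (P.hsig[k] > maxsig) maxsig = P.hsig[k];
  const double gcut = factor * maxsig;
  const double gcut2 = gcut * gcut;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      if (chain[i] == chain[j]) continue;
      const double dx = mimg(pos(i, 0) - pos(j, 0), L[0]);
      const double dy = mimg(pos(i, 1) - pos(j, 1), L[1]);
      const double dz = mimg(pos(i, 2) - pos(j, 2), L[2]);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= gcut2) continue;
      const double sig = P.hsig[type[i] + P.n * type[j]];
      const double cut = factor * sig;
      if (r2 < cut * cut) {
        const int si = seqpos[i], sj = seqpos[j];
        fmap(si, sj) += 1.0;
        if (si != sj) fmap(sj, si) += 1.0;
        if (with_energy) {
          double e, d;
          pair_ef(P, type[i], type[j], std::sqrt(r2), e, d, false);
          emap(si, sj) += e;
          if (si != sj) emap(sj, si) += e;
        }
      }
    }
  }
  return List::create(_["fmap"] = fmap, _["emap"] = emap);
}

// Grow n_chains self-avoiding random-walk chains of length chain_len with
// bond length r0, rejecting any bead closer than min_ratio * sigma_ij to a
// previously placed non-bonded bead.  Chain centres start with z in
// [zlo, zhi].  Uses a cell grid over the box for O(1) neighbour queries.
// [[Rcpp::export]]
NumericMatrix cpp_insert_chains(int n_chains, int chain_len,
                                NumericVector sig1, NumericVector box,
                                double zlo, double zhi, double r0,
                                double min_ratio, int seed,
                                int bead_tries, int chain_tries) {
  std::mt19937_64 rng((unsigned long long)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::normal_distribution<double> gauss(0.0, 1.0);
  const double L[3] = {box[0], box[1], box[2]};
  double maxsig = 0.0;
  for (int i = 0; i < chain_len; ++i)
    if (sig1[i] > maxsig) maxsig = sig1[i];
  const double cell = std::max(maxsig * min_ratio, 1e-3);
  const int nc[3] = {std::max(1, (int)(L[0] / cell)),
                     std::max(1, (int)(L[1] / cell)),
                     std::max(1, (int)(L[2] / cell))};
  std::vector<std::vector<int>> grid(nc[0] * nc[1] * nc[2]);
  std::vector<double> X, Y, Z, S;
  auto cellof = [&](double x, double y, double z) {
    int a = (int)(x / L[0] * nc[0]) % nc[0];
    int b = (int)(y / L[1] * nc[1]) % nc[1];
    int c = (int)(z / L[2] * nc[2]) % nc[2];
    if (a < 0) a += nc[0];
    if (b < 0) b += nc[1];
    if (c < 0) c += nc[2];
    return (a * nc[1] + b) * nc[2] + c;
  };
  auto wrap1 = [](double v, double Lx) { return v - Lx * std::floor(v / Lx); };
  // clash against globally committed beads (skip indices >= skip_from for
  // the growing chain: its beads are checked separately so a failed chain
  // can be discarded)
  auto clash = [&](double x, double y, double z, double sig,
                   const std::vector<double> &cx,
                   const std::vector<double> &cy,
                   const std::vector<double> &cz,
                   const std::vector<double> &cs, int upto,
                   int skip_bonded) {
    // committed beads via grid
    int a0 = (int)(x / L[0] * nc[0]);
    int b0 = (int)(y / L[1] * nc[1]);
    int c0 = (int)(z / L[2] * nc[2]);
    for (int da = -1; da <= 1; ++da)
      for (int db = -1; db <= 1; ++db)
        for (int dc = -1; dc <= 1; ++dc) {
          int a = (a0 + da + nc[0]) % nc[0];
          int b = (b0 + db + nc[1]) % nc[1];
          int c = (c0 + dc + nc[2]) % nc[2];
          for (int j : grid[(a * nc[1] + b) * nc[2] + c]) {
            const double dx = mimg(x - X[j], L[0]);
            const double dy = mimg(y - Y[j], L[1]);
            const double dz = mimg(z - Z[j], L[2]);
            const double lim = min_ratio * 0.5 * (sig + S[j]);
            if (dx * dx + dy * dy + dz * dz < lim * lim) return true;
          }
        }
    // beads of the growing chain (all but the bonded predecessor)
    for (int j = 0; j < upto - skip_bonded; ++j) {
      const double dx = mimg(x - cx[j], L[0]);
      const double dy = mimg(y - cy[j], L[1]);
      const double dz = mimg(z - cz[j], L[2]);
      const double lim = min_ratio * 0.5 * (sig + cs[j]);
      if (dx * dx + dy * dy + dz * dz < lim * lim) return true;
    }
    return false;
  };
  NumericMatrix out(n_chains * chain_len, 3);
  for (int ch = 0; ch < n_chains; ++ch) {
    bool placed = false;
    for (int ct = 0; ct < chain_tries && !placed; ++ct) {
      std::vector<double> cx(chain_len), cy(chain_len), cz(chain_len),
          cs(chain_len);
      double x = unif(rng) * L[0];
      double y = unif(rng) * L[1];
      double z = zlo + unif(rng) * (zhi - zlo);
      x = wrap1(x, L[0]); y = wrap1(y, L[1]); z = wrap1(z, L[2]);
      if (clash(x, y, z, sig1[0], cx, cy, cz, cs, 0, 0)) continue;
      cx[0] = x; cy[0] = y; cz[0] = z; cs[0] = sig1[0];
      bool ok = true;
      for (int k = 1; k < chain_len && ok; ++k) {
        bool found = false;
        for (int bt = 0; bt < bead_tries; ++bt) {
          double ux = gauss(rng), uy = gauss(rng), uz = gauss(rng);
          const double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
          double px = wrap1(cx[k - 1] + r0 * ux / nrm, L[0]);
          double py = wrap1(cy[k - 1] + r0 * uy / nrm, L[1]);
          double pz = wrap1(cz[k - 1] + r0 * uz / nrm, L[2]);
          if (clash(px, py, pz, sig1[k], cx, cy, cz, cs, k, 1)) continue;
          cx[k] = px; cy[k] = py; cz[k] = pz; cs[k] = sig1[k];
          found = true;
          break;
        }
        ok = found;
      }
      if (!ok) continue;
      for (int k = 0; k < chain_len; ++k) {
        const int idx = ch * chain_len + k;
        out(idx, 0) = cx[k]; out(idx, 1) = cy[k]; out(idx, 2) = cz[k];
        X.push_back(cx[k]); Y.push_back(cy[k]); Z.push_back(cz[k]);
        S.push_back(cs[k]);
        grid[cellof(cx[k], cy[k], cz[k])].push_back((int)X.size() - 1);
      }
      placed = true;
    }
    if (!placed) stop("chain insertion failed (chain %d of %d)", ch + 1,
                      n_chains);
  }
  return out;
}

// minimum r / sigma_ij between a candidate chain and existing beads
// (used for overlap rejection during system construction)
// [[Rcpp::export]]
double cpp_min_sigma_ratio(NumericMatrix existing, NumericMatrix cand,
                           NumericVector box, NumericVector sig_existing,
                           NumericVector sig_cand) {
  const double L[3] = {box[0], box[1], box[2]};
  double best = R_PosInf;
  for (int i = 0; i < cand.nrow(); ++i) {
    for (int j = 0; j < existing.nrow(); ++j) {
      const double dx = mimg(cand(i, 0) - existing(j, 0), L[0]);
      const double dy = mimg(cand(i, 1) - existing(j, 1), L[1]);
      const double dz = mimg(cand(i, 2) - existing(j, 2), L[2]);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double ratio = r / (0.5 * (sig_cand[i] + sig_existing[j]));
      if (ratio < best) best = ratio;
    }
  }
  return best;
}
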