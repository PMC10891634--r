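// Compact periodic Langevin simulator: rigid 3-site water, monovalent ions,
// frozen wall atoms. Lennard-Jones with C1 switching, Coulomb with a
// reaction-field beyond-cutoff correction, BAOAB splitting with SHAKE/RATTLE
// water constraints, an adaptive-biasing-force accumulator along the ion z
// coordinate, and a constant-field crossing monitor.
//
// Internal units: Angstrom, kJ/mol, g/mol, e; the derived time unit is
// 0.1 ps (dt in these units = dt_fs / 100).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>

using namespace Rcpp;

static const double KB = 0.0083144621;      // kJ/mol/K
static const double COULOMB = 1389.35457;   // kJ Angstrom / mol / e^2

struct System {
  int n;
  std::vector<double> x, y, z;
  std::vector<double> vx, vy, vz;
  std::vector<double> mass, charge, eps, rmh; // per-atom LJ: eps, Rmin/2
  std::vector<int> mol;                        // molecule id (-1 = isolated)
  std::vector<char> wall;                      // frozen
  double box[3];
  // water constraint triplets (0-based O,H1,H2)
  std::vector<int> wO, wH1, wH2;
  double dOH, dHH;
};

struct NonBonded {
  double r_on2, r_off2, denom3; // switching
  double krf, crf, rc2;         // reaction field
};

struct NeighborList {
  std::vector<int> pi, pj;
  std::vector<double> epsij, rmin2ij, qqC; // per-pair parameters
  std::vector<double> x0, y0, z0;
  double skin;
  bool built = false;
};

static inline double wrap(double d, double L) {
  double t = d / L;
  int n = (int)(t >= 0.0 ? t + 0.5 : t - 0.5);
  return d - L * n;
}

static void build_neighbors(const System& S, const NonBonded& NB,
                            NeighborList& NL) {
  const double rl = std::sqrt(NB.r_off2) + NL.skin;
  const double rl2 = rl * rl;
  NL.pi.clear(); NL.pj.clear();
  NL.epsij.clear(); NL.rmin2ij.clear(); NL.qqC.clear();
  for (int i = 0; i < S.n; ++i) {
    for (int j = i + 1; j < S.n; ++j) {
      if (S.mol[i] >= 0 && S.mol[i] == S.mol[j]) continue;
      if (S.wall[i] && S.wall[j]) continue;
      double dx = wrap(S.x[i] - S.x[j], S.box[0]);
      double dy = wrap(S.y[i] - S.y[j], S.box[1]);
      double dz = wrap(S.z[i] - S.z[j], S.box[2]);
      if (dx * dx + dy * dy + dz * dz < rl2) {
        NL.pi.push_back(i); NL.pj.push_back(j);
        NL.epsij.push_back(std::sqrt(S.eps[i] * S.eps[j]));
        double rm = S.rmh[i] + S.rmh[j];
        NL.rmin2ij.push_back(rm * rm);
        NL.qqC.push_back(COULOMB * S.charge[i] * S.charge[j]);
      }
    }
  }
  NL.x0 = S.x; NL.y0 = S.y; NL.z0 = S.z;
  NL.built = true;
}

static bool need_rebuild(const System& S, const NeighborList& NL) {
  if (!NL.built) return true;
  const double lim2 = 0.25 * NL.skin * NL.skin;
  for (int i = 0; i < S.n; ++i) {
    if (S.wall[i]) continue;
    double dx = S.x[i] - NL.x0[i];
    double dy = S.y[i] - NL.y0[i];
    double dz = S.z[i] - NL.z0[i];
    if (dx * dx + dy * dy + dz * dz > lim2) return true;
  }
  return false;
}

// LJ (switched) + reaction-field Coulomb over the pair list.
// Returns potential energy; fills fx/fy/fz (not zeroed here).
static double pair_forces(const System& S, const NonBonded& NB,
                          const NeighborList& NL,
                          std::vector<double>& fx, std::vector<double>& fy,
                          std::vector<double>& fz,
                          double* e_lj_out = nullptr,
                          double* e_coul_out = nullptr) {
  double e_lj = 0.0, e_coul = 0.0;
  const size_t np = NL.pi.size();
  for (size_t p = 0; p < np; ++p) {
    const int i = NL.pi[p], j = NL.pj[p];
    double dx = wrap(S.x[i] - S.x[j], S.box[0]);
    double dy = wrap(S.y[i] - S.y[j], S.box[1]);
    double dz = wrap(S.z[i] - S.z[j], S.box[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= NB.r_off2) continue;
    double dvdr2 = 0.0; // d(V)/d(r^2)
    // Lennard-Jones with CHARMM-style C1 switching on the potential
    double epsij = NL.epsij[p];
    if (epsij > 0.0) {
      double a = NL.rmin2ij[p] / r2;
      double a3 = a * a * a;
      double vlj = epsij * (a3 * a3 - 2.0 * a3);
      double dvlj = -6.0 * epsij * (a3 * a3 - a3) / r2;
      double sw = 1.0, dsw = 0.0;
      if (r2 > NB.r_on2) {
        double t = NB.r_off2 - r2;
        sw = t * t * (NB.r_off2 + 2.0 * r2 - 3.0 * NB.r_on2) / NB.denom3;
        dsw = 6.0 * t * (NB.r_on2 - r2) / NB.denom3;
      }
      e_lj += vlj * sw;
      dvdr2 += dvlj * sw + vlj * dsw;
    }
    // reaction-field Coulomb (force and potential vanish at the cutoff
    // for the conducting-boundary krf)
    double qq = NL.qqC[p];
    if (qq != 0.0) {
      double rinv = 1.0 / std::sqrt(r2);
      e_coul += qq * (rinv + NB.krf * r2 - NB.crf);
      dvdr2 += qq * (-0.5 * rinv / r2 + NB.krf);
    }
    double f = -2.0 * dvdr2;
    fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
    fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
  }
  if (e_lj_out) *e_lj_out = e_lj;
  if (e_coul_out) *e_coul_out = e_coul;
  return e_lj + e_coul;
}

// classic SHAKE on the three water constraints: corrections act along the
// pre-drift constraint vectors (`rx0` arrays), which keeps the scheme
// time-reversible; velocities updated by the position corrections divided
// by dt_sub (pass 0 to skip)
static void shake(System& S, const std::vector<double>& x0,
                  const std::vector<double>& y0,
                  const std::vector<double>& z0,
                  double dt_sub, double tol, int maxit) {
  const size_t nw = S.wO.size();
  for (size_t w = 0; w < nw; ++w) {
    int a[3] = {S.wO[w], S.wH1[w], S.wH2[w]};
    double d2[3] = {S.dOH * S.dOH, S.dOH * S.dOH, S.dHH * S.dHH};
    int pa[3] = {0, 0, 1}, pb[3] = {1, 2, 2};
    double ox[3], oy[3], oz[3];
    for (int k = 0; k < 3; ++k) {
      ox[k] = S.x[a[k]]; oy[k] = S.y[a[k]]; oz[k] = S.z[a[k]];
    }
    // reference (pre-drift) constraint vectors
    double r0x[3], r0y[3], r0z[3];
    for (int c = 0; c < 3; ++c) {
      int ia = a[pa[c]], ib = a[pb[c]];
      r0x[c] = x0[ia] - x0[ib];
      r0y[c] = y0[ia] - y0[ib];
      r0z[c] = z0[ia] - z0[ib];
    }
    for (int it = 0; it < maxit; ++it) {
      bool done = true;
      for (int c = 0; c < 3; ++c) {
        int ia = a[pa[c]], ib = a[pb[c]];
        double rx = S.x[ia] - S.x[ib];
        double ry = S.y[ia] - S.y[ib];
        double rz = S.z[ia] - S.z[ib];
        double r2 = rx * rx + ry * ry + rz * rz;
        double diff = r2 - d2[c];
        if (std::fabs(diff) > tol * d2[c]) {
          done = false;
          double rr0 = rx * r0x[c] + ry * r0y[c] + rz * r0z[c];
          double imab = 1.0 / S.mass[ia] + 1.0 / S.mass[ib];
          double g = diff / (2.0 * imab * rr0);
          S.x[ia] -= g * r0x[c] / S.mass[ia];
          S.x[ib] += g * r0x[c] / S.mass[ib];
          S.y[ia] -= g * r0y[c] / S.mass[ia];
          S.y[ib] += g * r0y[c] / S.mass[ib];
          S.z[ia] -= g * r0z[c] / S.mass[ia];
          S.z[ib] += g * r0z[c] / S.mass[ib];
        }
      }
      if (done) break;
      if (it == maxit - 1) stop("SHAKE failed to converge on water %d", (int)w);
    }
    if (dt_sub > 0.0) {
      for (int k = 0; k < 3; ++k) {
        S.vx[a[k]] += (S.x[a[k]] - ox[k]) / dt_sub;
        S.vy[a[k]] += (S.y[a[k]] - oy[k]) / dt_sub;
        S.vz[a[k]] += (S.z[a[k]] - oz[k]) / dt_sub;
      }
    }
  }
}

// half drift of all mobile atoms followed by SHAKE against the pre-drift
// reference vectors (scratch arrays reused between steps)
static void drift_shake(System& S, double dts, std::vector<double>& px,
                        std::vector<double>& py, std::vector<double>& pz) {
  px = S.x; py = S.y; pz = S.z;
  for (int i = 0; i < S.n; ++i) {
    if (S.wall[i]) continue;
    S.x[i] += dts * S.vx[i];
    S.y[i] += dts * S.vy[i];
    S.z[i] += dts * S.vz[i];
  }
  shake(S, px, py, pz, dts, 1e-10, 500);
}

// RATTLE velocity projection onto the constraint manifold
static void rattle_v(System& S, int sweeps = 10, double tol = 1e-12) {
  const size_t nw = S.wO.size();
  for (size_t w = 0; w < nw; ++w) {
    int a[3] = {S.wO[w], S.wH1[w], S.wH2[w]};
    int pa[3] = {0, 0, 1}, pb[3] = {1, 2, 2};
    for (int it = 0; it < sweeps; ++it) {
      double worst = 0.0;
      for (int c = 0; c < 3; ++c) {
        int ia = a[pa[c]], ib = a[pb[c]];
        double rx = S.x[ia] - S.x[ib];
        double ry = S.y[ia] - S.y[ib];
        double rz = S.z[ia] - S.z[ib];
        double r2 = rx * rx + ry * ry + rz * rz;
        double rv = rx * (S.vx[ia] - S.vx[ib]) + ry * (S.vy[ia] - S.vy[ib]) +
                    rz * (S.vz[ia] - S.vz[ib]);
        double imab = 1.0 / S.mass[ia] + 1.0 / S.mass[ib];
        double g = rv / (imab * r2);
        S.vx[ia] -= g * rx / S.mass[ia]; S.vx[ib] += g * rx / S.mass[ib];
        S.vy[ia] -= g * ry / S.mass[ia]; S.vy[ib] += g * ry / S.mass[ib];
        S.vz[ia] -= g * rz / S.mass[ia]; S.vz[ib] += g * rz / S.mass[ib];
        worst = std::max(worst, std::fabs(rv));
      }
      if (worst < tol) break;
    }
  }
}

static System make_system(NumericMatrix xyz, NumericVector mass,
                          NumericVector charge, NumericVector eps,
                          NumericVector rmh, IntegerVector mol,
                          LogicalVector wall, NumericVector box,
                          IntegerMatrix water_idx) {
  System S;
  S.n = xyz.nrow();
  S.x.resize(S.n); S.y.resize(S.n); S.z.resize(S.n);
  S.vx.assign(S.n, 0.0); S.vy.assign(S.n, 0.0); S.vz.assign(S.n, 0.0);
  S.mass.resize(S.n); S.charge.resize(S.n);
  S.eps.resize(S.n); S.rmh.resize(S.n);
  S.mol.resize(S.n); S.wall.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.x[i] = xyz(i, 0); S.y[i] = xyz(i, 1); S.z[i] = xyz(i, 2);
    S.mass[i] = mass[i]; S.charge[i] = charge[i];
    S.eps[i] = eps[i]; S.rmh[i] = rmh[i];
    S.mol[i] = mol[i]; S.wall[i] = wall[i] ? 1 : 0;
  }
  for (int k = 0; k < 3; ++k) S.box[k] = box[k];
  for (int w = 0; w < water_idx.nrow(); ++w) {
    S.wO.push_back(water_idx(w, 0) - 1);
    S.wH1.push_back(water_idx(w, 1) - 1);
    S.wH2.push_back(water_idx(w, 2) - 1);
  }
  S.dOH = 0.9572;
  S.dHH = 2.0 * 0.9572 * std::sin(0.5 * 104.52 * M_PI / 180.0);
  return S;
}

static NonBonded make_nonbonded(double r_on, double r_off, double eps_rf) {
  NonBonded NB;
  NB.r_on2 = r_on * r_on;
  NB.r_off2 = r_off * r_off;
  double d = NB.r_off2 - NB.r_on2;
  NB.denom3 = d * d * d;
  NB.rc2 = NB.r_off2;
  double rc = r_off;
  if (R_finite(eps_rf)) {
    NB.krf = (eps_rf - 1.0) / ((2.0 * eps_rf + 1.0) * rc * rc * rc);
  } else {
    NB.krf = 1.0 / (2.0 * rc * rc * rc); // conducting boundary
  }
  NB.crf = 1.0 / rc + NB.krf * rc * rc;
  return NB;
}

// [[Rcpp::export(name = ".compute_forces_cpp")]]
List compute_forces_cpp(NumericMatrix xyz, NumericVector mass,
                        NumericVector charge, NumericVector eps,
                        NumericVector rmh, IntegerVector mol,
                        LogicalVector wall, NumericVector box,
                        IntegerMatrix water_idx, double r_on, double r_off,
                        double eps_rf) {
  System S = make_system(xyz, mass, charge, eps, rmh, mol, wall, box,
                         water_idx);
  NonBonded NB = make_nonbonded(r_on, r_off, eps_rf);
  NeighborList NL; NL.skin = 0.0;
  build_neighbors(S, NB, NL);
  std::vector<double> fx(S.n, 0.0), fy(S.n, 0.0), fz(S.n, 0.0);
  double e_lj = 0, e_coul = 0;
  double e = pair_forces(S, NB, NL, fx, fy, fz, &e_lj, &e_coul);
  NumericMatrix F(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i];
  }
  return List::create(_["forces"] = F, _["energy"] = e,
                      _["energy_lj"] = e_lj, _["energy_coulomb"] = e_coul);
}

// [[Rcpp::export(name = ".minimize_cpp")]]
NumericMatrix minimize_cpp(NumericMatrix xyz, NumericVector mass,
                           NumericVector charge, NumericVector eps,
                           NumericVector rmh, IntegerVector mol,
                           LogicalVector wall, NumericVector box,
                           IntegerMatrix water_idx, double r_on, double r_off,
                           double eps_rf, int n_steps, double max_disp) {
  System S = make_system(xyz, mass, charge, eps, rmh, mol, wall, box,
                         water_idx);
  NonBonded NB = make_nonbonded(r_on, r_off, eps_rf);
  NeighborList NL; NL.skin = 1.5;
  std::vector<double> fx(S.n), fy(S.n), fz(S.n);
  std::vector<double> px, py, pz;
  for (int step = 0; step < n_steps; ++step) {
    if (need_rebuild(S, NL)) build_neighbors(S, NB, NL);
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    pair_forces(S, NB, NL, fx, fy, fz);
    double fmax = 0.0;
    for (int i = 0; i < S.n; ++i) {
      if (S.wall[i]) continue;
      fmax = std::max(fmax, std::fabs(fx[i]));
      fmax = std::max(fmax, std::fabs(fy[i]));
      fmax = std::max(fmax, std::fabs(fz[i]));
    }
    if (fmax < 1e-8) break;
    double alpha = max_disp / fmax;
    px = S.x; py = S.y; pz = S.z;
    for (int i = 0; i < S.n; ++i) {
      if (S.wall[i]) continue;
      S.x[i] += alpha * fx[i];
      S.y[i] += alpha * fy[i];
      S.z[i] += alpha * fz[i];
    }
    shake(S, px, py, pz, 0.0, 1e-10, 500);
  }
  NumericMatrix out(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    out(i, 0) = S.x[i]; out(i, 1) = S.y[i]; out(i, 2) = S.z[i];
  }
  return out;
}

struct Thermostat {
  double dt, c1, kT;
  bool langevin;
};

static void init_velocities(System& S, double kT, std::mt19937_64& rng) {
  std::normal_distribution<double> N(0.0, 1.0);
  for (int i = 0; i < S.n; ++i) {
    if (S.wall[i]) continue;
    double s = std::sqrt(kT / S.mass[i]);
    S.vx[i] = s * N(rng); S.vy[i] = s * N(rng); S.vz[i] = s * N(rng);
  }
  rattle_v(S);
}

static double kinetic_energy(const System& S) {
  double ke = 0.0;
  for (int i = 0; i < S.n; ++i) {
    if (S.wall[i]) continue;
    ke += 0.5 * S.mass[i] * (S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] +
                             S.vz[i] * S.vz[i]);
  }
  return ke;
}

// shared BAOAB machinery; `extra` applies bias/restraint/field forces and is
// given the freshly computed physical forces each step
// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(NumericMatrix xyz, NumericVector mass, NumericVector charge,
                 NumericVector eps, NumericVector rmh, IntegerVector mol,
                 LogicalVector wall, NumericVector box,
                 IntegerMatrix water_idx, double r_on, double r_off,
                 double eps_rf, double dt_fs, double gamma_ps,
                 double temperature, int n_steps, int seed, int traj_stride,
                 int sample_stride, double field_E, int restrain_atom,
                 double k_trans, bool count_crossings, double pore_radius,
                 Nullable<NumericMatrix> velocities) {
  System S = make_system(xyz, mass, charge, eps, rmh, mol, wall, box,
                         water_idx);
  NonBonded NB = make_nonbonded(r_on, r_off, eps_rf);
  NeighborList NL; NL.skin = 1.5;
  const double dt = dt_fs / 100.0;           // 0.1 ps time unit
  const double gamma = gamma_ps * 0.1;       // per time unit
  const double kT = KB * temperature;
  const double c1 = std::exp(-gamma * dt);
  const double c2fac = std::sqrt((1.0 - c1 * c1) * kT);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> N(0.0, 1.0);

  if (velocities.isNotNull()) {
    NumericMatrix V(velocities);
    for (int i = 0; i < S.n; ++i) {
      S.vx[i] = V(i, 0); S.vy[i] = V(i, 1); S.vz[i] = V(i, 2);
    }
  } else {
    init_velocities(S, kT, rng);
  }

  int ndf = 0, nwat_mobile = 0;
  for (int i = 0; i < S.n; ++i) if (!S.wall[i]) ndf += 3;
  for (size_t w = 0; w < S.wO.size(); ++w)
    if (!S.wall[S.wO[w]]) nwat_mobile++;
  ndf -= 3 * nwat_mobile;

  std::vector<double> fx(S.n), fy(S.n), fz(S.n);
  std::vector<double> px, py, pz;
  const double Efield = field_E; // kJ/mol/Angstrom/e along +z
  const int ra = restrain_atom - 1; // -1 = none

  auto add_extra_forces = [&]() {
    if (Efield != 0.0) {
      for (int i = 0; i < S.n; ++i) {
        if (!S.wall[i] && S.charge[i] != 0.0) fz[i] += S.charge[i] * Efield;
      }
    }
    if (ra >= 0 && k_trans > 0.0) {
      fx[ra] -= k_trans * S.x[ra];
      fy[ra] -= k_trans * S.y[ra];
    }
  };

  auto eval_forces = [&]() {
    if (need_rebuild(S, NL)) build_neighbors(S, NB, NL);
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    double pe = pair_forces(S, NB, NL, fx, fy, fz);
    add_extra_forces();
    return pe;
  };

  double pe = eval_forces();
  std::vector<double> sample_t, sample_pe, sample_ke, sample_T;
  std::vector<NumericMatrix> frames;
  // crossing monitor state (wrapped coordinates)
  std::vector<double> zw_prev(S.n);
  std::vector<int> cross_up(S.n, 0), cross_down(S.n, 0);
  if (count_crossings) {
    for (int i = 0; i < S.n; ++i) zw_prev[i] = wrap(S.z[i], S.box[2]);
  }

  for (int step = 1; step <= n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < S.n; ++i) {
      if (S.wall[i]) continue;
      double h = 0.5 * dt / S.mass[i];
      S.vx[i] += h * fx[i]; S.vy[i] += h * fy[i]; S.vz[i] += h * fz[i];
    }
    rattle_v(S);
    // A: half drift + SHAKE
    drift_shake(S, 0.5 * dt, px, py, pz);
    // O: Ornstein-Uhlenbeck
    if (gamma > 0.0) {
      for (int i = 0; i < S.n; ++i) {
        if (S.wall[i]) continue;
        double c2 = c2fac / std::sqrt(S.mass[i]);
        S.vx[i] = c1 * S.vx[i] + c2 * N(rng);
        S.vy[i] = c1 * S.vy[i] + c2 * N(rng);
        S.vz[i] = c1 * S.vz[i] + c2 * N(rng);
      }
      rattle_v(S);
    }
    // A: half drift + SHAKE
    drift_shake(S, 0.5 * dt, px, py, pz);
    // B: half kick with fresh forces
    pe = eval_forces();
    for (int i = 0; i < S.n; ++i) {
      if (S.wall[i]) continue;
      double h = 0.5 * dt / S.mass[i];
      S.vx[i] += h * fx[i]; S.vy[i] += h * fy[i]; S.vz[i] += h * fz[i];
    }
    rattle_v(S);

    if (count_crossings) {
      for (int i = 0; i < S.n; ++i) {
        if (S.wall[i] || S.charge[i] == 0.0 || S.mol[i] >= 0) continue;
        double zw = wrap(S.z[i], S.box[2]);
        if (zw * zw_prev[i] < 0.0 &&
            std::fabs(zw - zw_prev[i]) < 0.5 * S.box[2]) {
          double rx = wrap(S.x[i], S.box[0]);
          double ry = wrap(S.y[i], S.box[1]);
          if (std::sqrt(rx * rx + ry * ry) < pore_radius) {
            if (zw > 0) cross_up[i]++; else cross_down[i]++;
          }
        }
        zw_prev[i] = zw;
      }
    }

    if (sample_stride > 0 && step % sample_stride == 0) {
      double ke = kinetic_energy(S);
      sample_t.push_back(step * dt_fs / 1000.0); // ps
      sample_pe.push_back(pe);
      sample_ke.push_back(ke);
      sample_T.push_back(2.0 * ke / (ndf * KB));
    }
    if (traj_stride > 0 && step % traj_stride == 0) {
      NumericMatrix M(S.n, 3);
      for (int i = 0; i < S.n; ++i) {
        M(i, 0) = S.x[i]; M(i, 1) = S.y[i]; M(i, 2) = S.z[i];
      }
      frames.push_back(M);
    }
  }

  NumericMatrix Xf(S.n, 3), Vf(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    Xf(i, 0) = S.x[i]; Xf(i, 1) = S.y[i]; Xf(i, 2) = S.z[i];
    Vf(i, 0) = S.vx[i]; Vf(i, 1) = S.vy[i]; Vf(i, 2) = S.vz[i];
  }
  return List::create(
    _["xyz"] = Xf, _["velocities"] = Vf,
    _["frames"] = wrap(frames),
    _["samples"] = DataFrame::create(_["t_ps"] = sample_t,
                                     _["potential"] = sample_pe,
                                     _["kinetic"] = sample_ke,
                                     _["temperature"] = sample_T),
    _["ndf"] = ndf,
    _["crossings_up"] = IntegerVector(cross_up.begin(), cross_up.end()),
    _["crossings_down"] = IntegerVector(cross_down.begin(), cross_down.end()));
}

// ABF along the z coordinate of one tagged atom (the test ion). The
// accumulated quantity per bin is the physical z force on the ion; the bias
// opposes the running mean after a per-bin ramp-up.
// [[Rcpp::export(name = ".sim_abf_cpp")]]
List sim_abf_cpp(NumericMatrix xyz, NumericVector mass, NumericVector charge,
                 NumericVector eps, NumericVector rmh, IntegerVector mol,
                 LogicalVector wall, NumericVector box,
                 IntegerMatrix water_idx, double r_on, double r_off,
                 double eps_rf, double dt_fs, double gamma_ps,
                 double temperature, int n_steps, int seed, int ion_atom,
                 double cv_lo, double cv_hi, double bin_width, int ramp,
                 double k_trans, double k_wall, int traj_stride,
                 Nullable<NumericMatrix> velocities,
                 Nullable<NumericVector> bias_sum0,
                 Nullable<IntegerVector> bias_count0, int estimate_after) {
  System S = make_system(xyz, mass, charge, eps, rmh, mol, wall, box,
                         water_idx);
  NonBonded NB = make_nonbonded(r_on, r_off, eps_rf);
  NeighborList NL; NL.skin = 1.5;
  const double dt = dt_fs / 100.0;
  const double gamma = gamma_ps * 0.1;
  const double kT = KB * temperature;
  const double c1 = std::exp(-gamma * dt);
  const double c2fac = std::sqrt((1.0 - c1 * c1) * kT);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> N(0.0, 1.0);
  const int ion = ion_atom - 1;
  const int nbins = (int)std::ceil((cv_hi - cv_lo) / bin_width - 1e-9);

  // bias accumulators adapt over the whole run (self-flattening sampling);
  // estimate accumulators start after a burn-in so the reported mean force
  // is free of the adaptation transient
  std::vector<double> fsum(nbins, 0.0), bsum(nbins, 0.0);
  std::vector<int> fcount(nbins, 0), bcount(nbins, 0);
  if (bias_sum0.isNotNull()) {
    NumericVector b(bias_sum0);
    IntegerVector c(bias_count0);
    for (int k = 0; k < nbins && k < b.size(); ++k) {
      bsum[k] = b[k]; bcount[k] = c[k];
    }
  }
  int cur_step = 0;

  if (velocities.isNotNull()) {
    NumericMatrix V(velocities);
    for (int i = 0; i < S.n; ++i) {
      S.vx[i] = V(i, 0); S.vy[i] = V(i, 1); S.vz[i] = V(i, 2);
    }
  } else {
    init_velocities(S, kT, rng);
  }

  std::vector<double> fx(S.n), fy(S.n), fz(S.n);
  std::vector<double> px, py, pz;
  double fz_phys = 0.0; // physical z force on the ion, pre-bias

  auto eval_forces = [&]() {
    if (need_rebuild(S, NL)) build_neighbors(S, NB, NL);
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    pair_forces(S, NB, NL, fx, fy, fz);
    fz_phys = fz[ion];
    // transverse restraint to the pore axis
    fx[ion] -= k_trans * S.x[ion];
    fy[ion] -= k_trans * S.y[ion];
    // window boundary restraints (not part of the CV force)
    double xi = S.z[ion];
    if (xi < cv_lo) fz[ion] += k_wall * (cv_lo - xi);
    if (xi > cv_hi) fz[ion] -= k_wall * (xi - cv_hi);
    // accumulate and bias inside the window
    int b = (int)std::floor((xi - cv_lo) / bin_width);
    if (b >= 0 && b < nbins) {
      bsum[b] += fz_phys;
      bcount[b] += 1;
      if (cur_step >= estimate_after) {
        fsum[b] += fz_phys;
        fcount[b] += 1;
      }
      double mean = bsum[b] / bcount[b];
      double scale = bcount[b] >= ramp ? 1.0 :
        (double)bcount[b] / (double)ramp;
      fz[ion] -= scale * mean;
    }
  };

  eval_forces();
  std::vector<NumericMatrix> frames;
  for (int step = 1; step <= n_steps; ++step) {
    cur_step = step;
    for (int i = 0; i < S.n; ++i) {
      if (S.wall[i]) continue;
      double h = 0.5 * dt / S.mass[i];
      S.vx[i] += h * fx[i]; S.vy[i] += h * fy[i]; S.vz[i] += h * fz[i];
    }
    rattle_v(S);
    drift_shake(S, 0.5 * dt, px, py, pz);
    if (gamma > 0.0) {
      for (int i = 0; i < S.n; ++i) {
        if (S.wall[i]) continue;
        double c2 = c2fac / std::sqrt(S.mass[i]);
        S.vx[i] = c1 * S.vx[i] + c2 * N(rng);
        S.vy[i] = c1 * S.vy[i] + c2 * N(rng);
        S.vz[i] = c1 * S.vz[i] + c2 * N(rng);
      }
      rattle_v(S);
    }
    drift_shake(S, 0.5 * dt, px, py, pz);
    eval_forces();
    for (int i = 0; i < S.n; ++i) {
      if (S.wall[i]) continue;
      double h = 0.5 * dt / S.mass[i];
      S.vx[i] += h * fx[i]; S.vy[i] += h * fy[i]; S.vz[i] += h * fz[i];
    }
    rattle_v(S);
    if (traj_stride > 0 && step % traj_stride == 0) {
      NumericMatrix M(S.n, 3);
      for (int i = 0; i < S.n; ++i) {
        M(i, 0) = S.x[i]; M(i, 1) = S.y[i]; M(i, 2) = S.z[i];
      }
      frames.push_back(M);
    }
  }

  NumericMatrix Xf(S.n, 3), Vf(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    Xf(i, 0) = S.x[i]; Xf(i, 1) = S.y[i]; Xf(i, 2) = S.z[i];
    Vf(i, 0) = S.vx[i]; Vf(i, 1) = S.vy[i]; Vf(i, 2) = S.vz[i];
  }
  NumericVector centers(nbins);
  for (int b = 0; b < nbins; ++b) centers[b] = cv_lo + (b + 0.5) * bin_width;
  return List::create(
    _["bin_centers"] = centers,
    _["force_sum"] = NumericVector(fsum.begin(), fsum.end()),
    _["count"] = IntegerVector(fcount.begin(), fcount.end()),
    _["bias_sum"] = NumericVector(bsum.begin(), bsum.end()),
    _["bias_count"] = IntegerVector(bcount.begin(), bcount.end()),
    _["xyz"] = Xf, _["velocities"] = Vf, _["frames"] = wrap(frames));
}

// 1-D BAOAB Langevin + ABF on an analytic potential (0 flat, 1 harmonic,
// 2 double-well); validates the estimator against closed forms.
// [[Rcpp::export(name = ".abf1d_cpp")]]
List abf1d_cpp(int form, NumericVector pars, double lo, double hi,
               double bin_width, int ramp, int n_steps, double dt,
               double gamma, double kT, double mass, int seed, double x0,
               bool apply_bias) {
  const int nbins = (int)std::ceil((hi - lo) / bin_width - 1e-9);
  std::vector<double> fsum(nbins, 0.0);
  std::vector<int> fcount(nbins, 0);
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> N(0.0, 1.0);
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt((1.0 - c1 * c1) * kT / mass);
  const double k_wall = 200.0;
  double x = x0, v = std::sqrt(kT / mass) * N(rng);

  auto force = [&](double xx, double& fphys) {
    double f = 0.0;
    switch (form) {
      case 0: f = 0.0; break;
      case 1: f = -pars[0] * (xx - pars[1]); break;          // k, x0
      case 2: {                                              // height, b
        double h = pars[0], b = pars[1];
        f = -h * 4.0 * xx * (xx * xx - b * b) / (b * b * b * b);
        break;
      }
      default: stop("unknown landscape form");
    }
    fphys = f;
    if (xx < lo) f += k_wall * (lo - xx);
    if (xx > hi) f -= k_wall * (xx - hi);
    int bb = (int)std::floor((xx - lo) / bin_width);
    if (bb >= 0 && bb < nbins) {
      fsum[bb] += fphys;
      fcount[bb] += 1;
      if (apply_bias) {
        double mean = fsum[bb] / fcount[bb];
        double scale = fcount[bb] >= ramp ? 1.0 :
          (double)fcount[bb] / (double)ramp;
        f -= scale * mean;
      }
    }
    return f;
  };

  double fphys = 0.0;
  double f = force(x, fphys);
  for (int step = 0; step < n_steps; ++step) {
    v += 0.5 * dt * f / mass;
    x += 0.5 * dt * v;
    v = c1 * v + c2 * N(rng);
    x += 0.5 * dt * v;
    f = force(x, fphys);
    v += 0.5 * dt * f / mass;
  }
  NumericVector centers(nbins);
  for (int b = 0; b < nbins; ++b) centers[b] = lo + (b + 0.5) * bin_width;
  return List::create(
    _["bin_centers"] = centers,
    _["force_sum"] = NumericVector(fsum.begin(), fsum.end()),
    _["count"] = IntegerVector(fcount.begin(), fcount.end()),
    _["x_final"] = x);
}
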