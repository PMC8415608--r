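// Core numerical kernels for the coarse-grained bead-spring model:
// pairwise energies/forces under minimum image, Verlet-list construction,
// a BAOAB Langevin integrator, and an RDF histogram.
//
// Units: kcal/mol (energy), Angstrom (length), amu (mass), fs (time), K.
// Velocities are in A/fs; F_CONV converts (kcal/mol/A)/amu to A/fs^2.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <random>

using namespace Rcpp;

static const double F_CONV = 4.184e-4;          // (kcal/mol/A)/amu -> A/fs^2
static const double KB = 1.987204259e-3;        // kcal/(mol K)

struct FF {
  int ntype;
  std::vector<double> eps, lam, sig;            // ntype x ntype, row-major
  std::vector<double> qtype;                    // charge per type (e)
  std::vector<double> shift;                    // LJ energy shift per pair type
  double kc;                                    // 332.06371/dielectric
  double debye;                                 // screening length (A)
  double rc_lj, rc_coul, rc_max;
  bool shifted;
  double bond_k, bond_r0;                       // U = k (r - r0)^2
};

static inline double lj126(double eps, double sig, double r, double &du) {
  double sr = sig / r;
  double sr6 = sr * sr * sr; sr6 *= sr6;
  double sr12 = sr6 * sr6;
  du = 4.0 * eps * (-12.0 * sr12 + 6.0 * sr6) / r;
  return 4.0 * eps * (sr12 - sr6);
}

// Ashbaugh-Hatch pair energy and dU/dr (no cutoff handling here)
static inline double ah_pair(double eps, double lam, double sig, double r,
                             double &du) {
  double dulj;
  double ulj = lj126(eps, sig, r, dulj);
  double rmin = std::pow(2.0, 1.0 / 6.0) * sig;
  if (r <= rmin) {
    du = dulj;
    return ulj + (1.0 - lam) * eps;
  }
  du = lam * dulj;
  return lam * ulj;
}

static FF make_ff(const NumericMatrix &eps, const NumericMatrix &lam,
                  const NumericMatrix &sig, const NumericVector &qtype,
                  const List &globals) {
  FF ff;
  ff.ntype = eps.nrow();
  int nt = ff.ntype;
  ff.eps.assign(nt * nt, 0.0);
  ff.lam.assign(nt * nt, 0.0);
  ff.sig.assign(nt * nt, 0.0);
  ff.qtype.assign(qtype.begin(), qtype.end());
  ff.kc = as<double>(globals["kc"]);
  ff.debye = as<double>(globals["debye"]);
  ff.rc_lj = as<double>(globals["rc_lj"]);
  ff.rc_coul = as<double>(globals["rc_coul"]);
  ff.shifted = as<bool>(globals["shifted"]);
  ff.bond_k = as<double>(globals["bond_k"]);
  ff.bond_r0 = as<double>(globals["bond_r0"]);
  ff.rc_max = std::max(ff.rc_lj, ff.rc_coul);
  ff.shift.assign(nt * nt, 0.0);
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < nt; ++j) {
      ff.eps[i * nt + j] = eps(i, j);
      ff.lam[i * nt + j] = lam(i, j);
      ff.sig[i * nt + j] = sig(i, j);
      if (ff.shifted) {
        double du;
        ff.shift[i * nt + j] =
            lam(i, j) * lj126(eps(i, j), sig(i, j), ff.rc_lj, du);
      }
    }
  return ff;
}

static inline void min_image(double &dx, double L) {
  dx -= L * std::round(dx / L);
}

typedef std::unordered_set<long long> ExclSet;

static ExclSet make_excl(const IntegerMatrix &bonds, int n) {
  ExclSet ex;
  for (int b = 0; b < bonds.nrow(); ++b) {
    long long i = bonds(b, 0), j = bonds(b, 1);
    ex.insert(i * (long long)n + j);
    ex.insert(j * (long long)n + i);
  }
  return ex;
}

// Verlet neighbour list within rlist over `members` (all beads for the
// short-range list, charged beads only for the electrostatic list)
static void build_nlist(const std::vector<double> &x, int n,
                        const double *box, double rlist, const ExclSet &ex,
                        const std::vector<int> &members,
                        std::vector<std::vector<int>> &nl) {
  nl.assign(n, {});
  double rl2 = rlist * rlist;
  int m = (int)members.size();
  for (int a = 0; a < m - 1; ++a) {
    int i = members[a];
    for (int b = a + 1; b < m; ++b) {
      int j = members[b];
      double dx = x[3 * i] - x[3 * j];
      double dy = x[3 * i + 1] - x[3 * j + 1];
      double dz = x[3 * i + 2] - x[3 * j + 2];
      min_image(dx, box[0]); min_image(dy, box[1]); min_image(dz, box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < rl2 && ex.find((long long)i * n + j) == ex.end())
        nl[i].push_back(j);
    }
  }
}

static std::vector<int> all_members(int n) {
  std::vector<int> v(n);
  for (int i = 0; i < n; ++i) v[i] = i;
  return v;
}

static std::vector<int> charged_members(const IntegerVector &type,
                                        const FF &ff) {
  std::vector<int> v;
  for (int i = 0; i < type.size(); ++i)
    if (ff.qtype[type[i]] != 0.0) v.push_back(i);
  return v;
}

struct Energies { double e_lj, e_coul, e_bond; };

static Energies forces(const std::vector<double> &x, int n, const double *box,
                       const IntegerVector &type, const IntegerMatrix &bonds,
                       const FF &ff,
                       const std::vector<std::vector<int>> &nl_lj,
                       const std::vector<std::vector<int>> &nl_coul,
                       std::vector<double> &f) {
  Energies en = {0.0, 0.0, 0.0};
  std::fill(f.begin(), f.end(), 0.0);
  int nt = ff.ntype;
  double rc_lj2 = ff.rc_lj * ff.rc_lj, rc_c2 = ff.rc_coul * ff.rc_coul;
  for (int i = 0; i < n; ++i) {
    int ti = type[i];
    for (int j : nl_lj[i]) {
      double dx = x[3 * i] - x[3 * j];
      double dy = x[3 * i + 1] - x[3 * j + 1];
      double dz = x[3 * i + 2] - x[3 * j + 2];
      min_image(dx, box[0]); min_image(dy, box[1]); min_image(dz, box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc_lj2) continue;
      int tj = type[j];
      double r = std::sqrt(r2);
      double du;
      double u = ah_pair(ff.eps[ti * nt + tj], ff.lam[ti * nt + tj],
                         ff.sig[ti * nt + tj], r, du);
      en.e_lj += u - ff.shift[ti * nt + tj];
      double fac = -du / r;            // F_i = -dU/dr * rhat
      f[3 * i] += fac * dx; f[3 * i + 1] += fac * dy; f[3 * i + 2] += fac * dz;
      f[3 * j] -= fac * dx; f[3 * j + 1] -= fac * dy; f[3 * j + 2] -= fac * dz;
    }
    double qi = ff.qtype[ti];
    if (qi == 0.0) continue;
    for (int j : nl_coul[i]) {
      double qq = qi * ff.qtype[type[j]];
      if (qq == 0.0) continue;
      double dx = x[3 * i] - x[3 * j];
      double dy = x[3 * i + 1] - x[3 * j + 1];
      double dz = x[3 * i + 2] - x[3 * j + 2];
      min_image(dx, box[0]); min_image(dy, box[1]); min_image(dz, box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc_c2) continue;
      double r = std::sqrt(r2);
      double u = ff.kc * qq * std::exp(-r / ff.debye) / r;
      double ushift = ff.shifted
        ? ff.kc * qq * std::exp(-ff.rc_coul / ff.debye) / ff.rc_coul : 0.0;
      en.e_coul += u - ushift;
      double du = -u * (1.0 / r + 1.0 / ff.debye);
      double fac = -du / r;
      f[3 * i] += fac * dx; f[3 * i + 1] += fac * dy; f[3 * i + 2] += fac * dz;
      f[3 * j] -= fac * dx; f[3 * j + 1] -= fac * dy; f[3 * j + 2] -= fac * dz;
    }
  }
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    min_image(dx, box[0]); min_image(dy, box[1]); min_image(dz, box[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - ff.bond_r0;
    en.e_bond += ff.bond_k * dr * dr;
    double du = 2.0 * ff.bond_k * dr;
    double fac = -du / r;
    f[3 * i] += fac * dx; f[3 * i + 1] += fac * dy; f[3 * i + 2] += fac * dz;
    f[3 * j] -= fac * dx; f[3 * j + 1] -= fac * dy; f[3 * j + 2] -= fac * dz;
  }
  return en;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, NumericVector box, IntegerVector type,
                       IntegerMatrix bonds, NumericMatrix epsM,
                       NumericMatrix lamM, NumericMatrix sigM,
                       NumericVector qtype, List globals) {
  int n = pos.nrow();
  FF ff = make_ff(epsM, lamM, sigM, qtype, globals);
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);
  ExclSet ex = make_excl(bonds, n);
  std::vector<std::vector<int>> nl_lj, nl_coul;
  build_nlist(x, n, box.begin(), ff.rc_lj, ex, all_members(n), nl_lj);
  build_nlist(x, n, box.begin(), ff.rc_coul, ex, charged_members(type, ff),
              nl_coul);
  std::vector<double> f(3 * n);
  Energies en = forces(x, n, box.begin(), type, bonds, ff, nl_lj, nl_coul, f);
  NumericMatrix fout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) fout(i, k) = f[3 * i + k];
  return List::create(_["e_lj"] = en.e_lj, _["e_coul"] = en.e_coul,
                      _["e_bond"] = en.e_bond, _["forces"] = fout);
}

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos, NumericVector box, IntegerVector type,
                      IntegerMatrix bonds, NumericMatrix epsM,
                      NumericMatrix lamM, NumericMatrix sigM,
                      NumericVector qtype, NumericVector mass_bead,
                      List globals, double dt, double temperature,
                      double gamma_ps, int n_equil, int n_prod,
                      int sample_interval, int seed, double skin,
                      double fmax) {
  int n = pos.nrow();
  FF ff = make_ff(epsM, lamM, sigM, qtype, globals);
  ExclSet ex = make_excl(bonds, n);
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = pos(i, k);

  std::mt19937_64 rng((unsigned long long)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  // effective mass in kcal/mol fs^2/A^2 so that a = F/m_eff
  std::vector<double> meff(n);
  for (int i = 0; i < n; ++i) meff[i] = mass_bead[i] / F_CONV;

  // Maxwell-Boltzmann velocities (zero for T = 0)
  for (int i = 0; i < n; ++i) {
    double s = temperature > 0.0 ? std::sqrt(KB * temperature / meff[i]) : 0.0;
    for (int k = 0; k < 3; ++k) v[3 * i + k] = s * gauss(rng);
  }

  double gamma = gamma_ps * 1e-3;               // ps^-1 -> fs^-1
  bool nve = (gamma <= 0.0);
  double c1 = nve ? 1.0 : std::exp(-gamma * dt);
  double c2 = nve ? 0.0 : std::sqrt(1.0 - c1 * c1);

  std::vector<std::vector<int>> nl_lj, nl_coul;
  std::vector<double> xref(3 * n);
  std::vector<int> all = all_members(n);
  std::vector<int> charged = charged_members(type, ff);
  double half_skin2 = 0.25 * skin * skin;
  build_nlist(x, n, box.begin(), ff.rc_lj + skin, ex, all, nl_lj);
  build_nlist(x, n, box.begin(), ff.rc_coul + skin, ex, charged, nl_coul);
  xref = x;
  Energies en = forces(x, n, box.begin(), type, bonds, ff, nl_lj, nl_coul, f);

  int n_steps = n_equil + n_prod;
  int nf = sample_interval > 0 ? n_prod / sample_interval : 0;
  NumericVector frames(Dimension(n, 3, std::max(nf, 1)));
  std::vector<double> log_t, log_T, log_ke, log_lj, log_coul, log_bond;
  log_t.reserve(nf); log_T.reserve(nf); log_ke.reserve(nf);
  log_lj.reserve(nf); log_coul.reserve(nf); log_bond.reserve(nf);
  int iframe = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        v[3 * i + k] += 0.5 * dt * f[3 * i + k] / meff[i];
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // O
    if (!nve) {
      for (int i = 0; i < n; ++i) {
        double s = std::sqrt(KB * temperature / meff[i]);
        for (int k = 0; k < 3; ++k)
          v[3 * i + k] = c1 * v[3 * i + k] + c2 * s * gauss(rng);
      }
    }
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];

    // neighbour-list refresh on displacement criterion
    double maxd2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double dx = x[3 * i] - xref[3 * i];
      double dy = x[3 * i + 1] - xref[3 * i + 1];
      double dz = x[3 * i + 2] - xref[3 * i + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > maxd2) maxd2 = d2;
    }
    if (maxd2 > half_skin2) {
      build_nlist(x, n, box.begin(), ff.rc_lj + skin, ex, all, nl_lj);
      build_nlist(x, n, box.begin(), ff.rc_coul + skin, ex, charged, nl_coul);
      xref = x;
    }

    en = forces(x, n, box.begin(), type, bonds, ff, nl_lj, nl_coul, f);
    for (int i = 0; i < 3 * n; ++i) {
      if (!std::isfinite(f[i]) || std::fabs(f[i]) > fmax)
        stop("instability: |force| exceeded %g kcal/mol/A at step %d "
             "(bead %d)", fmax, step, (int)(i / 3) + 1);
    }
    // B
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        v[3 * i + k] += 0.5 * dt * f[3 * i + k] / meff[i];

    if (step > n_equil && sample_interval > 0 &&
        (step - n_equil) % sample_interval == 0 && iframe < nf) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i) {
        double v2 = v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                    v[3 * i + 2] * v[3 * i + 2];
        ke += 0.5 * meff[i] * v2;
      }
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          frames[iframe * 3 * n + k * n + i] = x[3 * i + k];
      log_t.push_back((double)step * dt);
      log_ke.push_back(ke);
      log_T.push_back(2.0 * ke / (3.0 * n * KB));
      log_lj.push_back(en.e_lj);
      log_coul.push_back(en.e_coul);
      log_bond.push_back(en.e_bond);
      ++iframe;
    }
  }

  NumericMatrix xout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      xout(i, k) = x[3 * i + k];
      vout(i, k) = v[3 * i + k];
    }
  return List::create(
      _["frames"] = frames, _["n_frames"] = iframe,
      _["time_fs"] = wrap(log_t), _["temperature"] = wrap(log_T),
      _["kinetic"] = wrap(log_ke), _["e_lj"] = wrap(log_lj),
      _["e_coul"] = wrap(log_coul), _["e_bond"] = wrap(log_bond),
      _["positions"] = xout, _["velocities"] = vout);
}

// Minimum image distance over all non-bonded bead pairs (packing
// diagnostics).
// [[Rcpp::export]]
double cpp_min_dist(NumericMatrix pos, NumericVector box,
                    IntegerMatrix bonds) {
  int n = pos.nrow();
  ExclSet ex = make_excl(bonds, n);
  double best = R_PosInf;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (ex.find((long long)i * n + j) != ex.end()) continue;
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      min_image(dx, box[0]); min_image(dy, box[1]); min_image(dz, box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
  }
  return std::sqrt(best);
}

// Pair-distance histogram for g(r), excluding bonded pairs.
// frames: n x 3 x nf array; returns counts per bin (both members of each
// pair counted once; normalisation done in R).
// [[Rcpp::export]]
NumericVector cpp_rdf_hist(NumericVector frames, NumericVector box,
                           IntegerMatrix bonds, int n, int nf, double dr,
                           double rmax) {
  int nbin = (int)std::floor(rmax / dr);
  NumericVector hist(nbin);
  ExclSet ex = make_excl(bonds, n);
  double rmax2 = rmax * rmax;
  for (int fidx = 0; fidx < nf; ++fidx) {
    const double *fr = frames.begin() + (size_t)fidx * 3 * n;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (ex.find((long long)i * n + j) != ex.end()) continue;
        double dx = fr[i] - fr[j];
        double dy = fr[n + i] - fr[n + j];
        double dz = fr[2 * n + i] - fr[2 * n + j];
        min_image(dx, box[0]); min_image(dy, box[1]); min_image(dz, box[2]);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 < rmax2) {
          int b = (int)(std::sqrt(r2) / dr);
          if (b >= 0 && b < nbin) hist[b] += 2.0;  // count both i and j
        }
      }
    }
  }
  return hist;
}
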