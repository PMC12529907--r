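#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

// Units: Angstrom, kcal/mol, amu, fs. Degrees are converted to radians
// before entering this layer.
static const double FCONV = 4.184e-4;   // (kcal/mol/A)/amu -> A/fs^2
static const double KB    = 0.0019872041; // kcal/mol/K

struct System {
  NumericMatrix coords;      // N x 3 (working copy)
  NumericVector box;         // 3 edge lengths, orthorhombic
  IntegerVector type;        // 0-based type ids
  NumericMatrix eps, sig;    // ntype x ntype pair tables
  IntegerMatrix bonds;       // nb x 2, 0-based
  NumericVector bond_kb, bond_b0;
  IntegerMatrix angles;      // na x 3, 0-based
  NumericVector ang_kt, ang_t0; // kcal/mol/rad^2, rad
  std::unordered_set<long long> excl;
  double cutoff;
  bool shift;                // energy-shifted LJ at cutoff
  NumericVector mass;
};

static inline long long pkey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * n + j;
}

static System unpack(List sys) {
  System s;
  s.coords  = clone(as<NumericMatrix>(sys["coords"]));
  s.box     = as<NumericVector>(sys["box"]);
  s.type    = as<IntegerVector>(sys["type"]);
  s.eps     = as<NumericMatrix>(sys["eps"]);
  s.sig     = as<NumericMatrix>(sys["sig"]);
  s.bonds   = as<IntegerMatrix>(sys["bonds"]);
  s.bond_kb = as<NumericVector>(sys["bond_kb"]);
  s.bond_b0 = as<NumericVector>(sys["bond_b0"]);
  s.angles  = as<IntegerMatrix>(sys["angles"]);
  s.ang_kt  = as<NumericVector>(sys["ang_kt"]);
  s.ang_t0  = as<NumericVector>(sys["ang_t0"]);
  s.cutoff  = as<double>(sys["cutoff"]);
  s.shift   = as<bool>(sys["shift"]);
  s.mass    = as<NumericVector>(sys["mass"]);
  IntegerMatrix ex = as<IntegerMatrix>(sys["excl"]);
  int n = s.coords.nrow();
  for (int k = 0; k < ex.nrow(); ++k)
    s.excl.insert(pkey(ex(k, 0), ex(k, 1), n));
  return s;
}

static inline void min_image(double* d, const NumericVector& box) {
  for (int a = 0; a < 3; ++a) {
    double L = box[a];
    if (L > 0) d[a] -= L * std::round(d[a] / L);
  }
}

// Computes energies, forces and the pair/bonded virial W = sum r.f
// (for the instantaneous pressure used by the toy barostat).
static void energy_forces(const System& s, const NumericMatrix& x,
                          double& e_bond, double& e_angle, double& e_lj,
                          NumericMatrix& f, double& virial) {
  int n = x.nrow();
  e_bond = e_angle = e_lj = 0.0;
  virial = 0.0;
  std::fill(f.begin(), f.end(), 0.0);
  double rc2 = s.cutoff * s.cutoff;

  // Lennard-Jones, O(N^2) minimum-image loop (toy scale by design)
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (s.excl.count(pkey(i, j, n))) continue;
      double d[3] = { x(i,0)-x(j,0), x(i,1)-x(j,1), x(i,2)-x(j,2) };
      min_image(d, s.box);
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      if (r2 >= rc2 || r2 == 0.0) continue;
      int ti = s.type[i], tj = s.type[j];
      double eps = s.eps(ti, tj), sg = s.sig(ti, tj);
      if (eps == 0.0) continue;
      double s2 = sg*sg / r2, s6 = s2*s2*s2, s12 = s6*s6;
      double e = 4.0 * eps * (s12 - s6);
      if (s.shift) {
        double sc2 = sg*sg / rc2, sc6 = sc2*sc2*sc2;
        e -= 4.0 * eps * (sc6*sc6 - sc6);
      }
      e_lj += e;
      double fr = 24.0 * eps * (2.0*s12 - s6) / r2;  // (1/r)(-dU/dr)
      for (int a = 0; a < 3; ++a) {
        double fa = fr * d[a];
        f(i, a) += fa;
        f(j, a) -= fa;
        virial  += fa * d[a];
      }
    }
  }

  // Harmonic bonds, E = Kb (b - b0)^2  (CHARMM convention, no 1/2)
  for (int k = 0; k < s.bonds.nrow(); ++k) {
    int i = s.bonds(k,0), j = s.bonds(k,1);
    double d[3] = { x(i,0)-x(j,0), x(i,1)-x(j,1), x(i,2)-x(j,2) };
    min_image(d, s.box);
    double b = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    double db = b - s.bond_b0[k];
    e_bond += s.bond_kb[k] * db * db;
    if (b > 0) {
      double fr = -2.0 * s.bond_kb[k] * db / b;
      for (int a = 0; a < 3; ++a) {
        double fa = fr * d[a];
        f(i, a) += fa;
        f(j, a) -= fa;
        virial  += fa * d[a];
      }
    }
  }

  // Harmonic angles, E = Kt (theta - theta0)^2
  for (int k = 0; k < s.angles.nrow(); ++k) {
    int i = s.angles(k,0), j = s.angles(k,1), l = s.angles(k,2);
    double rij[3] = { x(i,0)-x(j,0), x(i,1)-x(j,1), x(i,2)-x(j,2) };
    double rlj[3] = { x(l,0)-x(j,0), x(l,1)-x(j,1), x(l,2)-x(j,2) };
    min_image(rij, s.box);
    min_image(rlj, s.box);
    double nij = std::sqrt(rij[0]*rij[0]+rij[1]*rij[1]+rij[2]*rij[2]);
    double nlj = std::sqrt(rlj[0]*rlj[0]+rlj[1]*rlj[1]+rlj[2]*rlj[2]);
    if (nij == 0 || nlj == 0) continue;
    double cth = (rij[0]*rlj[0]+rij[1]*rlj[1]+rij[2]*rlj[2]) / (nij*nlj);
    cth = std::max(-1.0, std::min(1.0, cth));
    double th = std::acos(cth);
    double dth = th - s.ang_t0[k];
    e_angle += s.ang_kt[k] * dth * dth;
    double sth = std::sqrt(1.0 - cth*cth);
    if (sth < 1e-8) sth = 1e-8;          // collinear guard
    // F_i = -dE/dr_i = (dE/dtheta / sin theta) * dc/dr_i  (dtheta/dc = -1/sin)
    double dEdth = 2.0 * s.ang_kt[k] * dth;
    double c = dEdth / sth;
    for (int a = 0; a < 3; ++a) {
      double fi = c * (rlj[a]/(nij*nlj) - cth*rij[a]/(nij*nij));
      double fl = c * (rij[a]/(nij*nlj) - cth*rlj[a]/(nlj*nlj));
      f(i, a) += fi;
      f(l, a) += fl;
      f(j, a) -= fi + fl;
      // internal forces sum to zero: virial via positions relative to j
      virial += fi * rij[a] + fl * rlj[a];
    }
  }
}

// [[Rcpp::export]]
List cpp_energy_forces(List sys) {
  System s = unpack(sys);
  int n = s.coords.nrow();
  NumericMatrix f(n, 3);
  double eb, ea, el, w;
  energy_forces(s, s.coords, eb, ea, el, f, w);
  return List::create(_["bond"] = eb, _["angle"] = ea, _["lj"] = el,
                      _["total"] = eb + ea + el, _["forces"] = f,
                      _["virial"] = w);
}

static double kinetic(const NumericMatrix& v, const NumericVector& m) {
  double ke = 0.0;
  for (int i = 0; i < v.nrow(); ++i)
    ke += m[i] * (v(i,0)*v(i,0) + v(i,1)*v(i,1) + v(i,2)*v(i,2));
  return 0.5 * ke / FCONV;
}

// BAOAB Langevin integrator; gamma = 0 and T ignored gives plain
// velocity Verlet (NVE). Optional Berendsen-style cell scaling for NPT.
// [[Rcpp::export]]
List cpp_run_md(List sys, double dt, int n_steps, double temperature,
                double gamma_ps, std::string ensemble, double pressure_atm,
                double tau_p_fs, int stride, NumericMatrix vel0) {
  System s = unpack(sys);
  int n = s.coords.nrow();
  NumericMatrix x = s.coords;
  NumericMatrix v = clone(vel0);
  NumericMatrix f(n, 3);
  NumericVector box = clone(s.box);
  s.box = box;
  double eb, ea, el, w;
  energy_forces(s, x, eb, ea, el, f, w);

  double gamma = gamma_ps / 1000.0;       // 1/fs
  double c1 = std::exp(-gamma * dt);
  bool npt = (ensemble == "npt" || ensemble == "npt-semiiso");
  bool semi = (ensemble == "npt-semiiso");
  const double PCONV = 68568.3;           // kcal/mol/A^3 -> atm
  double betap = 4.6e-5;                  // 1/atm, water-like compressibility

  int n_out = n_steps / stride + 1;
  List frames(n_out);
  NumericMatrix boxes(n_out, 3);
  NumericVector t_ke(n_out), t_pe(n_out), t_temp(n_out), t_time(n_out);
  int out = 0;
  auto record = [&](int step) {
    frames[out] = clone(x);
    for (int a = 0; a < 3; ++a) boxes(out, a) = box[a];
    double ke = kinetic(v, s.mass);
    t_ke[out] = ke;
    t_pe[out] = eb + ea + el;
    t_temp[out] = 2.0 * ke / (3.0 * n * KB);
    t_time[out] = step * dt;
    ++out;
  };
  record(0);

  GetRNGstate();
  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < n; ++i)
      for (int a = 0; a < 3; ++a)
        v(i,a) += 0.5 * dt * f(i,a) / s.mass[i] * FCONV;
    // A
    for (int i = 0; i < n; ++i)
      for (int a = 0; a < 3; ++a)
        x(i,a) += 0.5 * dt * v(i,a);
    // O
    if (gamma > 0) {
      for (int i = 0; i < n; ++i) {
        double sv = std::sqrt((1.0 - c1*c1) * KB * temperature * FCONV / s.mass[i]);
        for (int a = 0; a < 3; ++a)
          v(i,a) = c1 * v(i,a) + sv * norm_rand();
      }
    }
    // A
    for (int i = 0; i < n; ++i)
      for (int a = 0; a < 3; ++a)
        x(i,a) += 0.5 * dt * v(i,a);
    // force refresh + B
    energy_forces(s, x, eb, ea, el, f, w);
    for (int i = 0; i < n; ++i)
      for (int a = 0; a < 3; ++a)
        v(i,a) += 0.5 * dt * f(i,a) / s.mass[i] * FCONV;

    if (npt) {
      double ke = kinetic(v, s.mass);
      double vol = box[0] * box[1] * box[2];
      double p = (2.0 * ke / 3.0 + w / 3.0) / vol * PCONV;
      double mu = std::cbrt(1.0 - betap * dt / tau_p_fs * (pressure_atm - p));
      mu = std::max(0.995, std::min(1.005, mu));
      if (semi) {
        double mul = mu * mu * mu;       // put full scaling in xy
        mul = std::sqrt(std::max(0.99, std::min(1.01, mul)));
        box[0] *= mul; box[1] *= mul;
        for (int i = 0; i < n; ++i) { x(i,0) *= mul; x(i,1) *= mul; }
      } else {
        for (int a = 0; a < 3; ++a) box[a] *= mu;
        for (int i = 0; i < n; ++i)
          for (int a = 0; a < 3; ++a) x(i,a) *= mu;
      }
    }

    double etot = eb + ea + el + kinetic(v, s.mass);
    if (!std::isfinite(etot) || std::fabs(etot) > 1e10) {
      PutRNGstate();
      stop("energy diverged at step %d (|E| > 1e10 kcal/mol); reduce the timestep", step);
    }
    if (step % stride == 0) record(step);
  }
  PutRNGstate();

  return List::create(_["frames"] = frames, _["boxes"] = boxes,
                      _["kinetic"] = t_ke, _["potential"] = t_pe,
                      _["temperature"] = t_temp, _["time_fs"] = t_time,
                      _["final_velocities"] = v);
}

// Steepest descent with backtracking; returns best-found configuration.
// [[Rcpp::export]]
List cpp_minimize(List sys, int max_steps, double step0, double ftol) {
  System s = unpack(sys);
  int n = s.coords.nrow();
  NumericMatrix x = s.coords, f(n, 3), xtry(n, 3), ftry(n, 3);
  double eb, ea, el, w;
  energy_forces(s, x, eb, ea, el, f, w);
  double e = eb + ea + el;
  NumericVector trace(max_steps + 1);
  trace[0] = e;
  double alpha = step0;
  int it = 0;
  for (; it < max_steps; ++it) {
    double fmax = 0.0;
    for (int i = 0; i < n; ++i)
      for (int a = 0; a < 3; ++a)
        fmax = std::max(fmax, std::fabs(f(i,a)));
    if (fmax < ftol) break;
    bool accepted = false;
    for (int half = 0; half < 30; ++half) {
      double sc = alpha / fmax;
      for (int i = 0; i < n; ++i)
        for (int a = 0; a < 3; ++a)
          xtry(i,a) = x(i,a) + sc * f(i,a);
      double eb2, ea2, el2, w2;
      energy_forces(s, xtry, eb2, ea2, el2, ftry, w2);
      double e2 = eb2 + ea2 + el2;
      if (e2 < e) {
        x = clone(xtry);
        f = clone(ftry);
        e = e2;
        alpha = std::min(alpha * 1.2, 1.0);
        accepted = true;
        break;
      }
      alpha *= 0.5;
    }
    trace[it + 1] = e;
    if (!accepted) break;
  }
  return List::create(_["coords"] = x, _["energy"] = e,
                      _["trace"] = trace[Range(0, std::max(it, 0))],
                      _["n_steps"] = it);
}
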