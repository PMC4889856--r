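// Trajectory core: ion-gas interaction potential, analytic forces, and
// classical scattering of a drift-gas probe in the rigid ion's field.
//
// Internal units: Angstrom, Dalton, meV, elementary charge, ps.
// The probe is the equivalent one-body particle of reduced mass mu; the ion
// is held rigid at the origin and the gas orientation (for multi-site
// models) is frozen along a per-trajectory axis.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double COULOMB = 14399.6455;      // e^2/(4 pi eps0), meV * A
static const double MEV_TO_ACC = 9.64853329;   // (meV/A)/Da -> A/ps^2
static const double R_MIN_GUARD = 0.2;         // A, near-singularity guard

struct Gas {
  std::vector<double> offset;   // site offsets along axis, A
  std::vector<int> lj;          // LJ flag per site
  std::vector<double> charge;   // point charge per site, e
  double alpha;                 // polarizability, A^3
};

struct Ion {
  const double* xyz;            // n x 3, column-major (R matrix)
  const double* q;
  const double* eps;            // per-atom well depth vs this gas, meV
  const double* sig;            // per-atom diameter vs this gas, A
  int n;
  double x(int i) const { return xyz[i]; }
  double y(int i) const { return xyz[i + n]; }
  double z(int i) const { return xyz[i + 2 * n]; }
};

// potential energy (meV) and force on the probe center (meV/A).
// Returns false if any atom-site distance violates the guard radius.
static bool eval_vf(const Ion& ion, const Gas& gas,
                    const double r[3], const double u[3],
                    double& V, double F[3]) {
  V = 0.0;
  F[0] = F[1] = F[2] = 0.0;
  const int ns = (int)gas.offset.size();
  for (int s = 0; s < ns; ++s) {
    const double sp[3] = { r[0] + gas.offset[s] * u[0],
                           r[1] + gas.offset[s] * u[1],
                           r[2] + gas.offset[s] * u[2] };
    for (int i = 0; i < ion.n; ++i) {
      const double dx = sp[0] - ion.x(i);
      const double dy = sp[1] - ion.y(i);
      const double dz = sp[2] - ion.z(i);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < R_MIN_GUARD * R_MIN_GUARD) return false;
      if (gas.lj[s]) {
        const double s2 = ion.sig[i] * ion.sig[i] / d2;
        const double s6 = s2 * s2 * s2;
        const double s12 = s6 * s6;
        V += 4.0 * ion.eps[i] * (s12 - s6);
        const double fmag = 24.0 * ion.eps[i] * (2.0 * s12 - s6) / d2;
        F[0] += fmag * dx; F[1] += fmag * dy; F[2] += fmag * dz;
      }
      if (gas.charge[s] != 0.0) {
        const double d1 = std::sqrt(d2);
        const double vc = COULOMB * gas.charge[s] * ion.q[i] / d1;
        V += vc;
        const double fmag = vc / d2;
        F[0] += fmag * dx; F[1] += fmag * dy; F[2] += fmag * dz;
      }
    }
  }
  if (gas.alpha > 0.0) {
    // induced dipole at the gas center: V = -(alpha/2) |E|^2 (in e/A^2),
    // times the Coulomb prefactor; force via the (symmetric) field Jacobian
    double E[3] = {0, 0, 0};
    double J[6] = {0, 0, 0, 0, 0, 0};  // xx, yy, zz, xy, xz, yz
    for (int i = 0; i < ion.n; ++i) {
      const double dx = r[0] - ion.x(i);
      const double dy = r[1] - ion.y(i);
      const double dz = r[2] - ion.z(i);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < R_MIN_GUARD * R_MIN_GUARD) return false;
      const double d1 = std::sqrt(d2);
      const double d3 = d1 * d2;
      const double d5 = d3 * d2;
      const double qi = ion.q[i];
      E[0] += qi * dx / d3; E[1] += qi * dy / d3; E[2] += qi * dz / d3;
      J[0] += qi * (1.0 / d3 - 3.0 * dx * dx / d5);
      J[1] += qi * (1.0 / d3 - 3.0 * dy * dy / d5);
      J[2] += qi * (1.0 / d3 - 3.0 * dz * dz / d5);
      J[3] += qi * (-3.0 * dx * dy / d5);
      J[4] += qi * (-3.0 * dx * dz / d5);
      J[5] += qi * (-3.0 * dy * dz / d5);
    }
    const double e2 = E[0] * E[0] + E[1] * E[1] + E[2] * E[2];
    V += -0.5 * gas.alpha * COULOMB * e2;
    // F = -(dV/dr) = alpha * C * J^T E  (J symmetric)
    F[0] += gas.alpha * COULOMB * (J[0] * E[0] + J[3] * E[1] + J[4] * E[2]);
    F[1] += gas.alpha * COULOMB * (J[3] * E[0] + J[1] * E[1] + J[5] * E[2]);
    F[2] += gas.alpha * COULOMB * (J[4] * E[0] + J[5] * E[1] + J[2] * E[2]);
  }
  return true;
}

static Gas gas_from_list(const List& g) {
  Gas gas;
  NumericVector off = g["offset"];
  IntegerVector lj = g["lj"];
  NumericVector ch = g["charge"];
  gas.offset.assign(off.begin(), off.end());
  gas.lj.assign(lj.begin(), lj.end());
  gas.charge.assign(ch.begin(), ch.end());
  gas.alpha = as<double>(g["alpha"]);
  return gas;
}

// [[Rcpp::export]]
List cpp_potential(NumericMatrix coords, NumericVector q, NumericVector eps,
                   NumericVector sig, List gas_list, NumericVector center,
                   NumericVector axis) {
  Ion ion = { REAL(coords), REAL(q), REAL(eps), REAL(sig), coords.nrow() };
  Gas gas = gas_from_list(gas_list);
  double r[3] = { center[0], center[1], center[2] };
  double u[3] = { axis[0], axis[1], axis[2] };
  double V, F[3];
  if (!eval_vf(ion, gas, r, u, V, F))
    stop("near-singularity: an atom-site distance fell below %.2f A", R_MIN_GUARD);
  // torque on the rigid gas about its center (relevant for multi-site gases):
  // tau = sum_s (site - center) x f_site. Recompute per-site forces cheaply
  // by finite rotation is unnecessary; use analytic per-site accumulation.
  double tau[3] = {0, 0, 0};
  const int ns = (int)gas.offset.size();
  for (int s = 0; s < ns; ++s) {
    if (gas.offset[s] == 0.0) continue;
    double fs[3] = {0, 0, 0};
    const double sp[3] = { r[0] + gas.offset[s] * u[0],
                           r[1] + gas.offset[s] * u[1],
                           r[2] + gas.offset[s] * u[2] };
    for (int i = 0; i < ion.n; ++i) {
      const double dx = sp[0] - ion.x(i);
      const double dy = sp[1] - ion.y(i);
      const double dz = sp[2] - ion.z(i);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (gas.lj[s]) {
        const double s2 = ion.sig[i] * ion.sig[i] / d2;
        const double s6 = s2 * s2 * s2;
        const double s12 = s6 * s6;
        const double fmag = 24.0 * ion.eps[i] * (2.0 * s12 - s6) / d2;
        fs[0] += fmag * dx; fs[1] += fmag * dy; fs[2] += fmag * dz;
      }
      if (gas.charge[s] != 0.0) {
        const double d1 = std::sqrt(d2);
        const double fmag = COULOMB * gas.charge[s] * ion.q[i] / (d1 * d2);
        fs[0] += fmag * dx; fs[1] += fmag * dy; fs[2] += fmag * dz;
      }
    }
    const double arm[3] = { gas.offset[s] * u[0], gas.offset[s] * u[1],
                            gas.offset[s] * u[2] };
    tau[0] += arm[1] * fs[2] - arm[2] * fs[1];
    tau[1] += arm[2] * fs[0] - arm[0] * fs[2];
    tau[2] += arm[0] * fs[1] - arm[1] * fs[0];
  }
  return List::create(_["energy"] = V,
                      _["force"] = NumericVector::create(F[0], F[1], F[2]),
                      _["torque"] = NumericVector::create(tau[0], tau[1], tau[2]));
}

// --- Cash-Karp RK45 with adaptive step ------------------------------------

struct Settings {
  double rtol, atol, energy_tol, init_dt, start_vfrac;
  int max_steps, max_retries;
};

struct TrajOut {
  double chi, drift;
  int steps, status;       // 0 ok, 1 trapped, 2 non-conservation, 3 singular
  double pos[3], vel[3];
};

static bool deriv(const Ion& ion, const Gas& gas, const double u[3],
                  double mu, const double y[6], double dy[6]) {
  double V, F[3];
  const double r[3] = { y[0], y[1], y[2] };
  if (!eval_vf(ion, gas, r, u, V, F)) return false;
  dy[0] = y[3]; dy[1] = y[4]; dy[2] = y[5];
  const double f = MEV_TO_ACC / mu;
  dy[3] = F[0] * f; dy[4] = F[1] * f; dy[5] = F[2] * f;
  return true;
}

// single attempted integration at a given rtol; returns status
static int integrate_once(const Ion& ion, const Gas& gas, const double u[3],
                          double mu, const double y0[6], double r_stop2,
                          double ke0, const Settings& st, double rtol,
                          TrajOut& out) {
  static const double a2 = 0.2, a3 = 0.3, a4 = 0.6, a5 = 1.0, a6 = 0.875;
  static const double b21 = 0.2;
  static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
  static const double b41 = 0.3, b42 = -0.9, b43 = 1.2;
  static const double b51 = -11.0 / 54.0, b52 = 2.5, b53 = -70.0 / 27.0,
                      b54 = 35.0 / 27.0;
  static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                      b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                      b65 = 253.0 / 4096.0;
  static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                      c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
  static const double d1 = c1 - 2825.0 / 27648.0, d3 = c3 - 18575.0 / 48384.0,
                      d4 = c4 - 13525.0 / 55296.0, d6 = c6 - 0.25,
                      d5 = -277.0 / 14336.0;
  (void)a2; (void)a3; (void)a4; (void)a5; (void)a6;

  double y[6], k1[6], k2[6], k3[6], k4[6], k5[6], k6[6], yt[6], yerr[6];
  std::copy(y0, y0 + 6, y);
  double dt = st.init_dt;
  int steps = 0;
  while (steps < st.max_steps) {
    if (!deriv(ion, gas, u, mu, y, k1)) return 3;
    bool accepted = false;
    while (!accepted) {
      for (int i = 0; i < 6; ++i) yt[i] = y[i] + dt * b21 * k1[i];
      if (!deriv(ion, gas, u, mu, yt, k2)) { dt *= 0.5; continue; }
      for (int i = 0; i < 6; ++i)
        yt[i] = y[i] + dt * (b31 * k1[i] + b32 * k2[i]);
      if (!deriv(ion, gas, u, mu, yt, k3)) { dt *= 0.5; continue; }
      for (int i = 0; i < 6; ++i)
        yt[i] = y[i] + dt * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
      if (!deriv(ion, gas, u, mu, yt, k4)) { dt *= 0.5; continue; }
      for (int i = 0; i < 6; ++i)
        yt[i] = y[i] + dt * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] +
                             b54 * k4[i]);
      if (!deriv(ion, gas, u, mu, yt, k5)) { dt *= 0.5; continue; }
      for (int i = 0; i < 6; ++i)
        yt[i] = y[i] + dt * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                             b64 * k4[i] + b65 * k5[i]);
      if (!deriv(ion, gas, u, mu, yt, k6)) { dt *= 0.5; continue; }
      double errmax = 0.0;
      for (int i = 0; i < 6; ++i) {
        yerr[i] = dt * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] + d5 * k5[i] +
                        d6 * k6[i]);
        const double ynew = y[i] + dt * (c1 * k1[i] + c3 * k3[i] +
                                         c4 * k4[i] + c6 * k6[i]);
        const double sc = st.atol + rtol * std::max(std::fabs(y[i]),
                                                    std::fabs(ynew));
        const double e = std::fabs(yerr[i]) / sc;
        if (e > errmax) errmax = e;
        yt[i] = ynew;
      }
      if (errmax <= 1.0) {
        accepted = true;
        std::copy(yt, yt + 6, y);
        double grow = 0.9 * std::pow(std::max(errmax, 1e-10), -0.2);
        if (grow > 5.0) grow = 5.0;
        dt *= grow;
      } else {
        double shrink = 0.9 * std::pow(errmax, -0.25);
        if (shrink < 0.1) shrink = 0.1;
        dt *= shrink;
        if (dt < 1e-12) return 3;
      }
    }
    ++steps;
    const double r2 = y[0] * y[0] + y[1] * y[1] + y[2] * y[2];
    const double rdotv = y[0] * y[3] + y[1] * y[4] + y[2] * y[5];
    if (r2 > r_stop2 && rdotv > 0.0) {
      double V, F[3];
      const double r[3] = { y[0], y[1], y[2] };
      if (!eval_vf(ion, gas, r, u, V, F)) return 3;
      const double v2 = y[3] * y[3] + y[4] * y[4] + y[5] * y[5];
      const double ke = 0.5 * mu * v2 / MEV_TO_ACC;
      out.drift = std::fabs((ke + V) - ke0) / ke0;
      out.steps = steps;
      for (int i = 0; i < 3; ++i) { out.pos[i] = y[i]; out.vel[i] = y[3 + i]; }
      return (out.drift <= st.energy_tol) ? 0 : 2;
    }
  }
  out.steps = steps;
  for (int i = 0; i < 3; ++i) { out.pos[i] = y[i]; out.vel[i] = y[3 + i]; }
  return 1;  // trapped / step cap
}

// start distance: |V| below start_vfrac * kinetic energy along the approach
static double find_start_x(const Ion& ion, const Gas& gas, const double u[3],
                           double b, double ke, double vfrac, double x_init) {
  double x = x_init;
  for (int iter = 0; iter < 60; ++iter) {
    const double r[3] = { -x, b, 0.0 };
    double V, F[3];
    if (eval_vf(ion, gas, r, u, V, F) && std::fabs(V) <= vfrac * ke) return x;
    x *= 1.25;
    if (x > 500.0) break;
  }
  return x;
}

static TrajOut scatter_one(const Ion& ion, const Gas& gas, const double u[3],
                           double mu, double b, double g, const Settings& st) {
  TrajOut out; out.chi = 0.0; out.drift = 0.0; out.steps = 0; out.status = 0;
  double rext = 0.0;
  for (int i = 0; i < ion.n; ++i) {
    const double r2 = ion.x(i) * ion.x(i) + ion.y(i) * ion.y(i) +
                      ion.z(i) * ion.z(i);
    if (r2 > rext) rext = r2;
  }
  rext = std::sqrt(rext);
  const double ke = 0.5 * mu * g * g / MEV_TO_ACC;
  const double x0 = find_start_x(ion, gas, u, b, ke, st.start_vfrac,
                                 rext + 6.0);
  const double r_stop2 = (x0 * x0 + b * b) * 1.0000001;
  double y0[6] = { -x0, b, 0.0, g, 0.0, 0.0 };
  double V, F[3];
  const double rs[3] = { y0[0], y0[1], y0[2] };
  if (!eval_vf(ion, gas, rs, u, V, F)) { out.status = 3; return out; }
  const double e0 = ke + V;
  double rtol = st.rtol;
  Settings stl = st;
  stl.init_dt = std::min(st.init_dt, 0.5 / g);
  for (int attempt = 0; attempt <= st.max_retries; ++attempt) {
    const int status = integrate_once(ion, gas, u, mu, y0, r_stop2, e0, stl,
                                      rtol, out);
    out.status = status;
    if (status == 0 || status == 1 || status == 3) break;
    rtol *= 0.1;  // non-conservation: tighten and retry
  }
  if (out.status == 0 || out.status == 2) {
    const double vn = std::sqrt(out.vel[0] * out.vel[0] +
                                out.vel[1] * out.vel[1] +
                                out.vel[2] * out.vel[2]);
    double ca = out.vel[0] / vn;  // incoming direction was +x
    if (ca > 1.0) ca = 1.0; if (ca < -1.0) ca = -1.0;
    out.chi = std::acos(ca);
  }
  return out;
}

static Settings settings_from_list(const List& s) {
  Settings st;
  st.rtol = as<double>(s["rtol"]);
  st.atol = as<double>(s["atol"]);
  st.energy_tol = as<double>(s["energy_tol"]);
  st.init_dt = as<double>(s["init_dt"]);
  st.start_vfrac = as<double>(s["start_vfrac"]);
  st.max_steps = as<int>(s["max_steps"]);
  st.max_retries = as<int>(s["max_retries"]);
  return st;
}

// [[Rcpp::export]]
List cpp_scatter(NumericMatrix coords, NumericVector q, NumericVector eps,
                 NumericVector sig, List gas_list, NumericVector axis,
                 double mu, double b, double g, List settings) {
  Ion ion = { REAL(coords), REAL(q), REAL(eps), REAL(sig), coords.nrow() };
  Gas gas = gas_from_list(gas_list);
  double u[3] = { axis[0], axis[1], axis[2] };
  Settings st = settings_from_list(settings);
  TrajOut out = scatter_one(ion, gas, u, mu, b, g, st);
  return List::create(
    _["chi"] = out.chi, _["energy_drift"] = out.drift,
    _["steps"] = out.steps, _["status"] = out.status,
    _["pos"] = NumericVector::create(out.pos[0], out.pos[1], out.pos[2]),
    _["vel"] = NumericVector::create(out.vel[0], out.vel[1], out.vel[2]));
}

// integrate from an arbitrary state until the exit radius (time-reversal
// and diagnostic checks)
// [[Rcpp::export]]
List cpp_propagate(NumericMatrix coords, NumericVector q, NumericVector eps,
                   NumericVector sig, List gas_list, NumericVector axis,
                   double mu, NumericVector pos0, NumericVector vel0,
                   double r_stop, List settings) {
  Ion ion = { REAL(coords), REAL(q), REAL(eps), REAL(sig), coords.nrow() };
  Gas gas = gas_from_list(gas_list);
  double u[3] = { axis[0], axis[1], axis[2] };
  Settings st = settings_from_list(settings);
  double y0[6] = { pos0[0], pos0[1], pos0[2], vel0[0], vel0[1], vel0[2] };
  const double g = std::sqrt(vel0[0] * vel0[0] + vel0[1] * vel0[1] +
                             vel0[2] * vel0[2]);
  st.init_dt = std::min(st.init_dt, 0.5 / g);
  const double ke = 0.5 * mu * g * g / MEV_TO_ACC;
  double V, F[3];
  const double rs[3] = { y0[0], y0[1], y0[2] };
  if (!eval_vf(ion, gas, rs, u, V, F)) stop("initial state inside guard radius");
  TrajOut out;
  const int status = integrate_once(ion, gas, u, mu, y0, r_stop * r_stop,
                                    ke + V, st, st.rtol, out);
  return List::create(
    _["status"] = status, _["steps"] = out.steps,
    _["energy_drift"] = out.drift,
    _["pos"] = NumericVector::create(out.pos[0], out.pos[1], out.pos[2]),
    _["vel"] = NumericVector::create(out.vel[0], out.vel[1], out.vel[2]));
}

// batch scattering over precomputed jobs; coords_list holds one rotated
// coordinate matrix per orientation, jobs columns: orient (1-based), g, b,
// ax, ay, az (frozen gas axis)
// [[Rcpp::export]]
List cpp_scatter_batch(List coords_list, NumericVector q, NumericVector eps,
                       NumericVector sig, List gas_list, double mu,
                       IntegerVector orient, NumericVector g, NumericVector b,
                       NumericMatrix axis, List settings) {
  Gas gas = gas_from_list(gas_list);
  Settings st = settings_from_list(settings);
  const int nj = orient.size();
  NumericVector chi(nj), drift(nj);
  IntegerVector steps(nj), status(nj);
  std::vector<NumericMatrix> mats;
  mats.reserve(coords_list.size());
  for (int i = 0; i < coords_list.size(); ++i)
    mats.push_back(as<NumericMatrix>(coords_list[i]));
  for (int j = 0; j < nj; ++j) {
    const NumericMatrix& cm = mats[orient[j] - 1];
    Ion ion = { REAL(cm), REAL(q), REAL(eps), REAL(sig), cm.nrow() };
    double u[3] = { axis(j, 0), axis(j, 1), axis(j, 2) };
    TrajOut out = scatter_one(ion, gas, u, mu, b[j], g[j], st);
    chi[j] = out.chi; drift[j] = out.drift;
    steps[j] = out.steps; status[j] = out.status;
    if (j % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["chi"] = chi, _["energy_drift"] = drift,
                      _["steps"] = steps, _["status"] = status);
}
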