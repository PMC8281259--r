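// Closed-loop seven-compartment lumped-parameter circulation model.
// State layout (11): V_ra V_rv V_la V_lv | Q_ra_rv Q_rv_pa Q_la_lv Q_lv_ao |
//                    P_ao P_sys P_pa     (CGS units: mL, mL/s, Barye)
// Parameter layout follows parameter_names() on the R side (45 entries).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Model {
  double hr, t_sas, t_svs, t_pws;
  // chamber params: [ra rv la lv] x {E, K1, K2, V0}
  double E[4], K1[4], K2[4], V0[4];
  // valve params: [ra_rv rv_pa la_lv lv_ao]
  double Rv[4], Lv[4];
  double C_ao, C_sys, R_sys_a, R_sys_v, C_pa, R_pa;
  double tc, tsa, tsv, tpw;

  explicit Model(const NumericVector& p) {
    hr = p[0]; t_sas = p[1]; t_svs = p[2]; t_pws = p[3];
    for (int c = 0; c < 4; ++c) {
      E[c]  = p[4 + 4 * c];
      K1[c] = p[5 + 4 * c];
      K2[c] = p[6 + 4 * c];
      V0[c] = p[7 + 4 * c];
    }
    for (int v = 0; v < 4; ++v) { Rv[v] = p[20 + v]; Lv[v] = p[24 + v]; }
    C_ao = p[28]; C_sys = p[29]; R_sys_a = p[30]; R_sys_v = p[31];
    C_pa = p[32]; R_pa = p[33];
    tc = 60.0 / hr;
    tsa = tc * t_sas;
    tsv = tc * t_svs;
    tpw = tc / t_pws;  // atrial activation delay, as printed
  }

  inline double wrap(double t) const {
    double m = t - std::floor(t / tc) * tc;
    return (m < 0) ? m + tc : (m >= tc ? m - tc : m);
  }

  // half-cosine activation windows; t = 0 at onset of ventricular systole
  inline void activation(double t, double& Aa, double& Av) const {
    double tmv = wrap(t);
    double tma = wrap(t + tsa - tpw);
    Av = (tmv < tsv) ? 0.5 * (1.0 - std::cos(2.0 * M_PI * tmv / tsv)) : 0.0;
    Aa = (tma < tsa) ? 0.5 * (1.0 - std::cos(2.0 * M_PI * tma / tsa)) : 0.0;
  }

  // elastance chamber: passive exponential + activated linear term
  inline double chamber(int c, double V, double A, bool& bad) const {
    double arg = K2[c] * (V - V0[c]);
    if (arg > 500.0) { bad = true; return 0.0; }
    return K1[c] * (std::exp(arg) - 1.0) + A * E[c] * (V - V0[c]);
  }

  // dx/dt; returns false on overflow/non-physical evaluation
  bool rhs(double t, const double* x, double* dx) const {
    bool bad = false;
    double Aa, Av;
    activation(t, Aa, Av);
    double P_ra = chamber(0, x[0], Aa, bad);
    double P_rv = chamber(1, x[1], Av, bad);
    double P_la = chamber(2, x[2], Aa, bad);
    double P_lv = chamber(3, x[3], Av, bad);
    if (bad) return false;
    double P_ao = x[8], P_sys = x[9], P_pa = x[10];
    // valves open on a strictly favourable gradient
    bool phiT = P_ra > P_rv, phiP = P_rv > P_pa;
    bool phiM = P_la > P_lv, phiA = P_lv > P_ao;
    double QT = x[4] * (phiT ? 1.0 : 0.0);
    double QP = x[5] * (phiP ? 1.0 : 0.0);
    double QM = x[6] * (phiM ? 1.0 : 0.0);
    double QA = x[7] * (phiA ? 1.0 : 0.0);
    double Q_sys_a = (P_ao - P_sys) / R_sys_a;
    double Q_sys_v = (P_sys - P_ra) / R_sys_v;
    double Q_pa = (P_pa - P_la) / R_pa;
    dx[0] = Q_sys_v - QT;
    dx[1] = QT - QP;
    dx[2] = Q_pa - QM;
    dx[3] = QM - QA;
    dx[4] = phiT ? (P_ra - P_rv - Rv[0] * x[4]) / Lv[0] : 0.0;
    dx[5] = phiP ? (P_rv - P_pa - Rv[1] * x[5]) / Lv[1] : 0.0;
    dx[6] = phiM ? (P_la - P_lv - Rv[2] * x[6]) / Lv[2] : 0.0;
    dx[7] = phiA ? (P_lv - P_ao - Rv[3] * x[7]) / Lv[3] : 0.0;
    dx[8]  = (QA - Q_sys_a) / C_ao;
    dx[9]  = (Q_sys_a - Q_sys_v) / C_sys;
    dx[10] = (QP - Q_pa) / C_pa;
    return true;
  }

  // zero the flow state of any valve whose gradient is non-favourable, and
  // forbid retrograde flow (perfect one-way valves)
  void clamp(double t, double* x) const {
    bool bad = false;
    double Aa, Av;
    activation(t, Aa, Av);
    double P_ra = chamber(0, x[0], Aa, bad);
    double P_rv = chamber(1, x[1], Av, bad);
    double P_la = chamber(2, x[2], Aa, bad);
    double P_lv = chamber(3, x[3], Av, bad);
    if (bad) return;
    bool open[4] = {P_ra > P_rv, P_rv > x[10], P_la > P_lv, P_lv > x[8]};
    for (int v = 0; v < 4; ++v)
      if (!open[v] || x[4 + v] < 0.0) x[4 + v] = 0.0;
  }
};

static bool rk4_step(const Model& m, double t, double dt, double* x) {
  double k1[11], k2[11], k3[11], k4[11], xt[11];
  if (!m.rhs(t, x, k1)) return false;
  for (int i = 0; i < 11; ++i) xt[i] = x[i] + 0.5 * dt * k1[i];
  if (!m.rhs(t + 0.5 * dt, xt, k2)) return false;
  for (int i = 0; i < 11; ++i) xt[i] = x[i] + 0.5 * dt * k2[i];
  if (!m.rhs(t + 0.5 * dt, xt, k3)) return false;
  for (int i = 0; i < 11; ++i) xt[i] = x[i] + dt * k3[i];
  if (!m.rhs(t + dt, xt, k4)) return false;
  for (int i = 0; i < 11; ++i)
    x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  m.clamp(t + dt, x);
  for (int i = 0; i < 11; ++i) if (!std::isfinite(x[i])) return false;
  // chamber volumes must stay positive
  for (int i = 0; i < 4; ++i) if (x[i] <= 0.0) return false;
  return true;
}

// [[Rcpp::export(name = ".lpn_rhs")]]
NumericVector lpn_rhs_cpp(double t, NumericVector state,
                          NumericVector params) {
  Model m(params);
  NumericVector dx(11);
  if (!m.rhs(t, REAL(state), REAL(dx)))
    stop("simulation diverged: chamber pressure overflow in RHS");
  return dx;
}

// Integrate to a periodic steady state; returns the last cycle on a uniform
// grid plus convergence bookkeeping.
// [[Rcpp::export(name = ".lpn_simulate")]]
List lpn_simulate_cpp(NumericVector params, int steps_per_cycle,
                      int max_cycles, double periodicity_tol) {
  Model m(params);
  const int ns = steps_per_cycle;
  const double dt = m.tc / ns;
  double x[11];
  for (int i = 0; i < 11; ++i) x[i] = params[34 + i];
  m.clamp(0.0, x);

  NumericMatrix buf(ns + 1, 11);
  std::vector<double> mean_prev(11, NA_REAL), mean_cur(11);
  bool converged = false, diverged = false;
  int cycles = 0;

  for (int c = 0; c < max_cycles && !converged && !diverged; ++c) {
    std::fill(mean_cur.begin(), mean_cur.end(), 0.0);
    for (int k = 0; k < ns; ++k) {
      for (int i = 0; i < 11; ++i) { buf(k, i) = x[i]; mean_cur[i] += x[i]; }
      double t = c * m.tc + k * dt;
      if (!rk4_step(m, t, dt, x)) { diverged = true; break; }
    }
    if (diverged) break;
    for (int i = 0; i < 11; ++i) buf(ns, i) = x[i];
    cycles = c + 1;
    for (int i = 0; i < 11; ++i) mean_cur[i] /= ns;
    if (c > 0) {
      double rel = 0.0;
      for (int i = 0; i < 11; ++i) {
        double den = std::max(std::fabs(mean_prev[i]), 1e-6);
        rel = std::max(rel, std::fabs(mean_cur[i] - mean_prev[i]) / den);
      }
      if (rel < periodicity_tol) converged = true;
    }
    mean_prev = mean_cur;
  }

  NumericVector time(ns + 1);
  for (int k = 0; k <= ns; ++k) time[k] = k * dt;
  return List::create(_["time"] = time, _["states"] = buf,
                      _["cycles"] = cycles, _["converged"] = converged,
                      _["diverged"] = diverged, _["t_c"] = m.tc);
}
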