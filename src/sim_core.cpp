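#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Quasi-static multi-unit lung driven by a prescribed ventilatory flow plan.
//
// Per sample the lung holds a shared gas volume; alveolar pressure is the
// root of  g == sum over open units of v_i(p),  with
//   v_i(p) = vmax_i * (1 - exp(-k_i * p))        (strain-stiffening units)
//   v_i(p) = vmax_i * k_i * p                    (linear units)
// Units open when p >= po_i and close when p <= pc_i (bistable in between),
// so the solve and the state update are iterated to a joint fixed point.

namespace {

struct Lung {
  const double *po, *pc, *vmax, *kk;
  const int *linear;
  int n;

  double vol_open(double p, const std::vector<int>& open) const {
    double g = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!open[i]) continue;
      g += linear[i] ? vmax[i] * kk[i] * p
                     : vmax[i] * (1.0 - std::exp(-kk[i] * p));
    }
    return g;
  }

  // tangent compliance dV/dP of the open units at pressure p
  double ctan(double p, const std::vector<int>& open) const {
    double c = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!open[i]) continue;
      c += linear[i] ? vmax[i] * kk[i]
                     : vmax[i] * kk[i] * std::exp(-kk[i] * p);
    }
    return c;
  }

  double cap_open(const std::vector<int>& open) const {
    // finite capacity of the open nonlinear units; Inf if any linear unit open
    double cap = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!open[i]) continue;
      if (linear[i]) return R_PosInf;
      cap += vmax[i];
    }
    return cap;
  }
};

const double P_FLOOR = -5.0, P_CEIL = 250.0;

// solve g = V(p) for p given a fixed open set (safeguarded Newton)
double solve_pressure(const Lung& lung, double g, const std::vector<int>& open,
                      double p0, bool& ok) {
  ok = true;
  if (g <= 0.0 && lung.vol_open(0.0, open) >= g) {
    // volumes can be mildly negative only through the linear branch;
    // bracket below zero in that case, else pressure is ~0
    if (g >= -1e-12) return 0.0;
  }
  double cap = lung.cap_open(open);
  if (std::isfinite(cap) && g >= cap * (1.0 - 1e-9)) { ok = false; return NA_REAL; }

  double lo = P_FLOOR, hi = P_CEIL;
  double p = std::min(std::max(p0, lo + 1e-6), hi - 1e-6);
  for (int it = 0; it < 60; ++it) {
    double f = lung.vol_open(p, open) - g;
    if (std::fabs(f) < 1e-10 * std::max(1.0, std::fabs(g))) return p;
    if (f > 0) hi = p; else lo = p;
    double d = lung.ctan(p, open);
    double step = (d > 1e-14) ? f / d : 0.0;
    double pn = p - step;
    if (!(pn > lo && pn < hi) || step == 0.0) pn = 0.5 * (lo + hi);
    p = pn;
  }
  double f = lung.vol_open(p, open) - g;
  if (std::fabs(f) > 1e-6 * std::max(1.0, std::fabs(g))) { ok = false; return NA_REAL; }
  return p;
}

// joint fixed point of pressure solve and hysteresis state update
double solve_with_states(const Lung& lung, double g, std::vector<int>& open,
                         double p0, bool& ok) {
  double p = p0;
  for (int it = 0; it < 400; ++it) {
    p = solve_pressure(lung, g, open, p, ok);
    while (!ok) {
      // capacity of the open set exhausted: pressure rises until the closed
      // unit with the lowest opening pressure recruits (avalanche, one by one)
      int j = -1; double pomin = R_PosInf;
      for (int i = 0; i < lung.n; ++i)
        if (!open[i] && lung.po[i] < pomin) { pomin = lung.po[i]; j = i; }
      if (j < 0) return NA_REAL;
      open[j] = 1;
      p = solve_pressure(lung, g, open, p0, ok);
    }
    bool changed = false;
    for (int i = 0; i < lung.n; ++i) {
      if (!open[i] && p >= lung.po[i]) { open[i] = 1; changed = true; }
      else if (open[i] && p <= lung.pc[i]) { open[i] = 0; changed = true; }
    }
    if (!changed) return p;
  }
  ok = true; // accept last iterate (rare ping-pong at a boundary)
  return p;
}

} // namespace

// [[Rcpp::export]]
List sim_core(NumericVector po, NumericVector pc, NumericVector vmax,
              NumericVector kk, IntegerVector linear_unit,
              IntegerVector mode,      // per sample: 0 insp (flow given), 1 passive exp, 2 hold
              NumericVector qvent,     // prescribed flow for mode 0 (ml/s)
              NumericVector peep,      // per-sample PEEP target for passive expiration
              IntegerVector open0,     // initial unit states
              double g0,               // initial ventilatory gas volume (ml)
              double r_aw, double r_exp,
              double f_osc, double amp_pp, double dt,
              IntegerVector snap_idx   // 1-based sample indices for state snapshots
) {
  const int ns = mode.size();
  const int nu = po.size();
  Lung lung{po.begin(), pc.begin(), vmax.begin(), kk.begin(),
            linear_unit.begin(), nu};

  std::vector<int> open(nu);
  for (int i = 0; i < nu; ++i) open[i] = open0[i];

  NumericVector out_palv(ns), out_vao(ns), out_ptr(ns), out_nopen(ns), out_gas(ns);
  const int nsnap = snap_idx.size();
  IntegerMatrix snap_open(nu, nsnap);
  NumericVector snap_palv(nsnap), snap_gas(nsnap), snap_t(nsnap);
  int isnap = 0;

  const double w = 2.0 * M_PI * f_osc;
  double g_vent = g0, g_osc = 0.0;
  bool ok = true;
  double p_prev = solve_with_states(lung, g_vent, open, peep[0], ok);
  if (!ok) stop("initial pressure solve failed");
  double p_slow_prev = p_prev;
  double q_prev = 0.0, qosc_prev = 0.0;

  for (int t = 0; t < ns; ++t) {
    double tt = t * dt;
    double q;
    switch (mode[t]) {
      case 0: q = qvent[t]; break;
      case 1: q = -(p_slow_prev - peep[t]) / r_exp; break;
      default: q = 0.0;
    }
    // trapezoidal accumulation keeps the emitted flow samples consistent
    // with trapezoidal re-integration on the analysis side
    g_vent += 0.5 * (q + q_prev) * dt;
    q_prev = q;

    // oscillation: flow source whose amplitude is servo-ed to keep the
    // tracheal pressure oscillation at amp_pp peak-to-peak
    double c = lung.ctan(std::max(p_prev, 0.0), open);
    double zmag = std::sqrt(r_aw * r_aw + 1.0 / (w * c * w * c));
    // cosine phase: the oscillatory gas volume (A/w) sin(w t) is zero-mean,
    // so the oscillation adds no DC volume to the lung
    double a = 0.5 * amp_pp / zmag;
    double qosc = a * std::cos(w * tt);
    g_osc += 0.5 * (qosc + qosc_prev) * dt;
    qosc_prev = qosc;

    double g_tot = g_vent + g_osc;
    double p = solve_with_states(lung, g_tot, open, p_prev, ok);
    if (!ok) stop("tidal volume undeliverable at sample %d (t = %.3f s)", t + 1, tt);
    double p_slow = solve_pressure(lung, g_vent, open, p, ok);
    if (!ok) p_slow = p;

    double vao = q + qosc;
    out_palv[t] = p;
    out_vao[t] = vao;
    out_ptr[t] = p + r_aw * vao;
    out_gas[t] = g_tot;
    int nop = 0; for (int i = 0; i < nu; ++i) nop += open[i];
    out_nopen[t] = nop;

    if (isnap < nsnap && snap_idx[isnap] == t + 1) {
      for (int i = 0; i < nu; ++i) snap_open(i, isnap) = open[i];
      snap_palv[isnap] = p;
      snap_gas[isnap] = g_tot;
      snap_t[isnap] = tt;
      ++isnap;
    }
    p_prev = p;
    p_slow_prev = p_slow;
  }

  return List::create(
    _["ptr"] = out_ptr, _["vao"] = out_vao, _["palv"] = out_palv,
    _["n_open"] = out_nopen, _["gas"] = out_gas,
    _["snap_open"] = snap_open, _["snap_palv"] = snap_palv,
    _["snap_gas"] = snap_gas, _["snap_t"] = snap_t);
}
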