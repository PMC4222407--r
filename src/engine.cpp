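// Implicit cable-equation integrator for a branched compartmental neuron.
//
// Voltage: backward Euler on the tree (Hines elimination: compartments are
// ordered so every parent precedes its children, giving one sweep up and one
// sweep down). Gates: exponential (Rush-Larsen) update against tabulated
// steady-state and exp(-dt/tau) curves, exact for fixed voltage over a step.
// Units: mV, ms, uS, nF, nA; calcium in mM.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct GateTab {
  int exponent;
  bool ca_dep;
  std::vector<double> inf;   // nv (voltage-gated) or nv*nlc col-major (ca_dep)
  std::vector<double> efac;  // exp(-dt/tau), nv
  std::vector<double> state; // one value per expressing compartment
};

struct Chan {
  double erev;
  bool ca_source;
  std::vector<int> comp;
  std::vector<double> gbar;
  std::vector<GateTab> gates;
};

static inline double interp1(const std::vector<double>& tab, double x,
                             double x0, double inv_dx, int n) {
  double u = (x - x0) * inv_dx;
  if (u <= 0) return tab[0];
  if (u >= n - 1) return tab[n - 1];
  int i = (int)u;
  double f = u - i;
  return tab[i] + f * (tab[i + 1] - tab[i]);
}

static inline double interp2(const std::vector<double>& tab, double v, double lc,
                             double v0, double inv_dv, int nv,
                             double c0, double inv_dc, int nc) {
  double uv = (v - v0) * inv_dv;
  double uc = (lc - c0) * inv_dc;
  if (uv < 0) uv = 0; if (uv > nv - 1) uv = nv - 1;
  if (uc < 0) uc = 0; if (uc > nc - 1) uc = nc - 1;
  int iv = (int)uv; if (iv > nv - 2) iv = nv - 2;
  int ic = (int)uc; if (ic > nc - 2) ic = nc - 2;
  double fv = uv - iv, fc = uc - ic;
  const double* col0 = &tab[(size_t)ic * nv];
  const double* col1 = &tab[(size_t)(ic + 1) * nv];
  double a = col0[iv] + fv * (col0[iv + 1] - col0[iv]);
  double b = col1[iv] + fv * (col1[iv + 1] - col1[iv]);
  return a + fc * (b - a);
}

static inline double ipow(double x, int n) {
  double r = 1.0;
  while (n-- > 0) r *= x;
  return r;
}

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(IntegerVector parent, NumericVector g_ax, NumericVector cm,
                NumericVector g_leak, double e_leak, List channels,
                List vgrid, List cagrid, List capool,
                double dt, int nsteps, List stim, List init, List record) {
  const int n = parent.size();
  const double vmin = as<double>(vgrid["vmin"]);
  const double dv = as<double>(vgrid["dv"]);
  const int nv = as<int>(vgrid["nv"]);
  const double inv_dv = 1.0 / dv;
  const double lcmin = as<double>(cagrid["lcmin"]);
  const double dlc = as<double>(cagrid["dlc"]);
  const int nlc = as<int>(cagrid["nlc"]);
  const double inv_dlc = 1.0 / dlc;

  const double ca_rest = as<double>(capool["rest"]);
  const double ca_tau = as<double>(capool["tau"]);
  const double ca_phi = as<double>(capool["phi"]);
  const double eca = as<double>(capool["eca"]);
  NumericVector area_cm2 = capool["area_cm2"];

  const int stim_mode = as<int>(stim["mode"]); // 0 cc, 1 vc
  const int stim_comp = as<int>(stim["comp"]);
  NumericVector stim_val = stim["value"];
  if (stim_val.size() < nsteps) stop("stimulus vector shorter than nsteps");

  IntegerVector rec_comp = record["comp"];
  const int stride = as<int>(record["stride"]);
  const bool rec_current = as<bool>(record["current"]);
  const int nrec_t = nsteps / stride;
  NumericMatrix rec(nrec_t, rec_comp.size());
  NumericVector irec(rec_current ? nrec_t : 0);

  // unpack channels
  const int nch = channels.size();
  std::vector<Chan> ch(nch);
  for (int c = 0; c < nch; ++c) {
    List L = channels[c];
    ch[c].erev = as<double>(L["erev"]);
    ch[c].ca_source = as<bool>(L["ca_source"]);
    IntegerVector comp = L["comp"];
    NumericVector gbar = L["gbar"];
    ch[c].comp.assign(comp.begin(), comp.end());
    ch[c].gbar.assign(gbar.begin(), gbar.end());
    List gl = L["gates"];
    ch[c].gates.resize(gl.size());
    for (int g = 0; g < gl.size(); ++g) {
      List G = gl[g];
      GateTab& gt = ch[c].gates[g];
      gt.exponent = as<int>(G["exponent"]);
      gt.ca_dep = as<bool>(G["ca_dep"]);
      NumericVector inf = G["inf"];
      NumericVector tau = G["tau"];
      gt.inf.assign(inf.begin(), inf.end());
      gt.efac.resize(tau.size());
      for (int i = 0; i < tau.size(); ++i) gt.efac[i] = std::exp(-dt / tau[i]);
      gt.state.assign(ch[c].comp.size(), 0.0);
    }
  }

  // state
  std::vector<double> v(n), ca(n, ca_rest);
  NumericVector v_init = init["v"];
  for (int i = 0; i < n; ++i) v[i] = v_init[i];
  if (init.containsElementNamed("ca") && !Rf_isNull(init["ca"])) {
    NumericVector ca_init = init["ca"];
    for (int i = 0; i < n; ++i) ca[i] = ca_init[i];
  }
  bool have_gates = init.containsElementNamed("gates") && !Rf_isNull(init["gates"]);
  if (have_gates) {
    NumericVector gs = init["gates"];
    int k = 0;
    for (int c = 0; c < nch; ++c)
      for (size_t g = 0; g < ch[c].gates.size(); ++g)
        for (size_t j = 0; j < ch[c].gates[g].state.size(); ++j)
          ch[c].gates[g].state[j] = gs[k++];
  } else {
    for (int c = 0; c < nch; ++c)
      for (size_t g = 0; g < ch[c].gates.size(); ++g) {
        GateTab& gt = ch[c].gates[g];
        for (size_t j = 0; j < ch[c].comp.size(); ++j) {
          int ci = ch[c].comp[j];
          gt.state[j] = gt.ca_dep
            ? interp2(gt.inf, v[ci], std::log10(ca[ci]), vmin, inv_dv, nv, lcmin, inv_dlc, nlc)
            : interp1(gt.inf, v[ci], vmin, inv_dv, nv);
        }
      }
  }

  std::vector<double> gtot(n), ge(n), d(n), rhs(n), vprev(n), ica(n);
  const double GBIG = 1e9;

  for (int t = 0; t < nsteps; ++t) {
    // 1. gate update (Rush-Larsen at v^n, ca^n)
    for (int c = 0; c < nch; ++c) {
      for (size_t g = 0; g < ch[c].gates.size(); ++g) {
        GateTab& gt = ch[c].gates[g];
        const bool cadep = gt.ca_dep;
        for (size_t j = 0; j < ch[c].comp.size(); ++j) {
          const int ci = ch[c].comp[j];
          const double vi = v[ci];
          const double inf = cadep
            ? interp2(gt.inf, vi, std::log10(ca[ci]), vmin, inv_dv, nv, lcmin, inv_dlc, nlc)
            : interp1(gt.inf, vi, vmin, inv_dv, nv);
          const double e = interp1(gt.efac, vi, vmin, inv_dv, nv);
          gt.state[j] = inf + (gt.state[j] - inf) * e;
        }
      }
    }
    // 2. accumulate conductances
    for (int i = 0; i < n; ++i) {
      gtot[i] = g_leak[i];
      ge[i] = g_leak[i] * e_leak;
    }
    for (int c = 0; c < nch; ++c) {
      const double erev = ch[c].erev;
      const size_t m = ch[c].comp.size();
      for (size_t j = 0; j < m; ++j) {
        double g = ch[c].gbar[j];
        for (size_t gg = 0; gg < ch[c].gates.size(); ++gg)
          g *= ipow(ch[c].gates[gg].state[j], ch[c].gates[gg].exponent);
        const int ci = ch[c].comp[j];
        gtot[ci] += g;
        ge[ci] += g * erev;
      }
    }
    // 3. assemble and solve (backward Euler, Hines)
    for (int i = 0; i < n; ++i) {
      vprev[i] = v[i];
      d[i] = cm[i] / dt + gtot[i];
      rhs[i] = cm[i] / dt * v[i] + ge[i];
    }
    for (int i = 1; i < n; ++i) {
      d[i] += g_ax[i];
      d[parent[i]] += g_ax[i];
    }
    if (stim_mode == 0) {
      rhs[stim_comp] += stim_val[t]; // nA
    } else {
      d[stim_comp] += GBIG;
      rhs[stim_comp] += GBIG * stim_val[t];
    }
    for (int i = n - 1; i >= 1; --i) {
      const double f = g_ax[i] / d[i];
      d[parent[i]] -= f * g_ax[i];
      rhs[parent[i]] += f * rhs[i];
    }
    v[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i)
      v[i] = (rhs[i] + g_ax[i] * v[parent[i]]) / d[i];

    // 4. calcium influx from Ca channels at v^{n+1}
    std::fill(ica.begin(), ica.end(), 0.0);
    bool any_ca = false;
    for (int c = 0; c < nch; ++c) {
      if (!ch[c].ca_source) continue;
      any_ca = true;
      for (size_t j = 0; j < ch[c].comp.size(); ++j) {
        double g = ch[c].gbar[j];
        for (size_t gg = 0; gg < ch[c].gates.size(); ++gg)
          g *= ipow(ch[c].gates[gg].state[j], ch[c].gates[gg].exponent);
        const int ci = ch[c].comp[j];
        ica[ci] += g * (v[ci] - eca); // nA, negative = inward
      }
    }
    if (any_ca) {
      for (int i = 0; i < n; ++i) {
        const double dens = std::fabs(ica[i]) * 1e-6 / area_cm2[i]; // mA/cm^2
        ca[i] += dt * (ca_phi * dens - (ca[i] - ca_rest) / ca_tau);
        if (ca[i] < ca_rest) ca[i] = ca_rest;
      }
    }

    // 5. record
    if ((t + 1) % stride == 0) {
      const int r = (t + 1) / stride - 1;
      for (int k = 0; k < rec_comp.size(); ++k) rec(r, k) = v[rec_comp[k]];
      if (rec_current) {
        const int k = stim_comp;
        double iax = 0.0;
        if (k > 0) iax += g_ax[k] * (v[k] - v[parent[k]]);
        for (int i = 1; i < n; ++i)
          if (parent[i] == k) iax += g_ax[i] * (v[k] - v[i]);
        irec[r] = cm[k] * (v[k] - vprev[k]) / dt + (gtot[k] * v[k] - ge[k]) + iax;
      }
    }
    if ((t & 63) == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(v[i]))
          stop("non-finite membrane potential in compartment %d at t = %.3f ms",
               i + 1, (t + 1) * dt);
    }
  }

  // pack final gate state
  int ngs = 0;
  for (int c = 0; c < nch; ++c)
    for (size_t g = 0; g < ch[c].gates.size(); ++g) ngs += ch[c].gates[g].state.size();
  NumericVector gfin(ngs);
  int k = 0;
  for (int c = 0; c < nch; ++c)
    for (size_t g = 0; g < ch[c].gates.size(); ++g)
      for (size_t j = 0; j < ch[c].gates[g].state.size(); ++j)
        gfin[k++] = ch[c].gates[g].state[j];

  return List::create(_["rec"] = rec, _["i_rec"] = irec,
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["gates"] = gfin,
                      _["ca"] = NumericVector(ca.begin(), ca.end()));
}
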