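// Compartmental cable integrator.
//
// Backward-Euler voltage update with staggered Rush-Larsen gate updates
// (exact exponential relaxation toward the tabulated steady state), the
// standard stable scheme for stiff Hodgkin-Huxley cable systems.  The
// implicit linear solve uses the Hines ordering (every parent precedes its
// children), giving an O(n) tree solve per step.
//
// Units: mV, ms, nA, uS, nF  (uS * mV = nA; nF * mV/ms = nA).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Packed {
  int n;
  IntegerVector parent;
  NumericVector cm, g_ax, g_leak;
  double e_leak;
  NumericMatrix chan_g;          // comps x channels
  NumericVector chan_e;
  LogicalVector chan_ca_gated, chan_is_ca;
  IntegerVector gate_chan;
  NumericVector gate_power;
  NumericMatrix gate_inf, gate_tau;  // grid x gates
  double v_min, dv;
  double ca_gain, ca_tau, ca_kd;
  int nchan, ngate, ngrid;
};

Packed unpack(const List& pm) {
  Packed p;
  p.n = as<int>(pm["n"]);
  p.parent = pm["parent"];
  p.cm = pm["cm"];
  p.g_ax = pm["g_ax"];
  p.g_leak = pm["g_leak"];
  p.e_leak = as<double>(pm["e_leak"]);
  p.chan_g = as<NumericMatrix>(pm["chan_g"]);
  p.chan_e = pm["chan_e"];
  p.chan_ca_gated = pm["chan_ca_gated"];
  p.chan_is_ca = pm["chan_is_ca"];
  p.gate_chan = pm["gate_chan"];
  p.gate_power = pm["gate_power"];
  p.gate_inf = as<NumericMatrix>(pm["gate_inf"]);
  p.gate_tau = as<NumericMatrix>(pm["gate_tau"]);
  p.v_min = as<double>(pm["v_min"]);
  p.dv = as<double>(pm["dv"]);
  p.ca_gain = as<double>(pm["ca_gain"]);
  p.ca_tau = as<double>(pm["ca_tau"]);
  p.ca_kd = as<double>(pm["ca_kd"]);
  p.nchan = p.chan_g.ncol();
  p.ngate = p.gate_chan.size();
  p.ngrid = p.gate_inf.nrow();
  return p;
}

inline double interp(const NumericMatrix& tab, int col, double v,
                     double v_min, double dv, int ngrid) {
  double x = (v - v_min) / dv;
  if (x <= 0.0) return tab(0, col);
  if (x >= ngrid - 1) return tab(ngrid - 1, col);
  int i = (int)x;
  double f = x - i;
  return tab(i, col) * (1.0 - f) + tab(i + 1, col) * f;
}

// Injected current into each compartment at time t (sources: rows of
// [comp, type(0 step/1 sine), amp_nA, freq_Hz, phase_deg, onset, offset]).
inline void inj_current(const NumericMatrix& src, double t,
                        std::vector<double>& iinj) {
  std::fill(iinj.begin(), iinj.end(), 0.0);
  for (int s = 0; s < src.nrow(); ++s) {
    if (t < src(s, 5) || t >= src(s, 6)) continue;
    int c = (int)src(s, 0);
    double amp = src(s, 2);
    if (src(s, 1) == 0.0) {
      iinj[c] += amp;
    } else {
      double w = 2.0 * M_PI * src(s, 3) * 1e-3;      // rad/ms
      double ph = src(s, 4) * M_PI / 180.0;
      iinj[c] += amp * std::sin(w * (t - src(s, 5)) + ph);
    }
  }
}

struct State {
  std::vector<double> v;
  std::vector<double> m;   // ngate x n, gate-major: m[g*n + i]
  std::vector<double> chi;
};

State init_state(const Packed& p, const List& init) {
  State st;
  st.v.resize(p.n);
  st.m.resize((size_t)p.ngate * p.n);
  st.chi.assign(p.n, 0.0);
  if (init.size() > 0 && init.containsElementNamed("v")) {
    NumericVector v0 = init["v"], m0 = init["m"], c0 = init["chi"];
    for (int i = 0; i < p.n; ++i) { st.v[i] = v0[i]; st.chi[i] = c0[i]; }
    for (size_t k = 0; k < st.m.size(); ++k) st.m[k] = m0[k];
  } else {
    double v0 = p.e_leak;
    for (int i = 0; i < p.n; ++i) st.v[i] = v0;
    for (int g = 0; g < p.ngate; ++g)
      for (int i = 0; i < p.n; ++i)
        st.m[(size_t)g * p.n + i] =
          interp(p.gate_inf, g, v0, p.v_min, p.dv, p.ngrid);
  }
  return st;
}

// One integration step; returns max |dV| over compartments.
double step(const Packed& p, State& st, const NumericMatrix& src,
            double t, double dt,
            std::vector<double>& gtot, std::vector<double>& getot,
            std::vector<double>& iinj, std::vector<double>& diag,
            std::vector<double>& rhs, std::vector<double>& open,
            std::vector<double>& ica) {
  // 1. gates: exact first-order relaxation at current V
  for (int g = 0; g < p.ngate; ++g) {
    double* mg = &st.m[(size_t)g * p.n];
    for (int i = 0; i < p.n; ++i) {
      double inf = interp(p.gate_inf, g, st.v[i], p.v_min, p.dv, p.ngrid);
      double tau = interp(p.gate_tau, g, st.v[i], p.v_min, p.dv, p.ngrid);
      mg[i] += (inf - mg[i]) * (1.0 - std::exp(-dt / tau));
    }
  }

  // 2. membrane conductances with updated gates
  std::fill(gtot.begin(), gtot.end(), 0.0);
  std::fill(getot.begin(), getot.end(), 0.0);
  std::fill(ica.begin(), ica.end(), 0.0);
  std::fill(open.begin(), open.end(), 1.0);
  for (int g = 0; g < p.ngate; ++g) {
    const double* mg = &st.m[(size_t)g * p.n];
    int c = p.gate_chan[g];
    double pw = p.gate_power[g];
    for (int i = 0; i < p.n; ++i) {
      double o = mg[i];
      if (pw == 2.0) o *= o;
      else if (pw != 1.0) o = std::pow(o, pw);
      open[(size_t)c * p.n + i] *= o;
    }
  }
  for (int c = 0; c < p.nchan; ++c) {
    double e = p.chan_e[c];
    bool cg = p.chan_ca_gated[c];
    bool is_ca = p.chan_is_ca[c];
    for (int i = 0; i < p.n; ++i) {
      double gb = p.chan_g(i, c);
      if (gb == 0.0) continue;
      double o = open[(size_t)c * p.n + i];
      if (cg) o *= st.chi[i] / (st.chi[i] + p.ca_kd);
      double gc = gb * o;
      gtot[i] += gc;
      getot[i] += gc * e;
      if (is_ca) ica[i] += gc * (st.v[i] - e);   // nA, inward negative
    }
  }

  // 3. implicit voltage update (Hines solve)
  inj_current(src, t + dt, iinj);
  for (int i = 0; i < p.n; ++i) {
    double a = p.cm[i] / dt;
    diag[i] = a + gtot[i] + p.g_leak[i];
    rhs[i] = a * st.v[i] + getot[i] + p.g_leak[i] * p.e_leak + iinj[i];
  }
  for (int i = 1; i < p.n; ++i) {
    diag[i] += p.g_ax[i];
    diag[p.parent[i]] += p.g_ax[i];
  }
  for (int i = p.n - 1; i >= 1; --i) {
    int pa = p.parent[i];
    double f = p.g_ax[i] / diag[i];
    diag[pa] -= f * p.g_ax[i];
    rhs[pa] += f * rhs[i];
  }
  double vnew0 = rhs[0] / diag[0];
  double dmax = std::fabs(vnew0 - st.v[0]);
  std::vector<double>& vn = rhs;  // reuse rhs as solution buffer
  vn[0] = vnew0;
  for (int i = 1; i < p.n; ++i) {
    vn[i] = (rhs[i] + p.g_ax[i] * vn[p.parent[i]]) / diag[i];
    double d = std::fabs(vn[i] - st.v[i]);
    if (d > dmax) dmax = d;
  }
  for (int i = 0; i < p.n; ++i) st.v[i] = vn[i];

  // 4. calcium pool: influx from inward Ca current, first-order decay
  double ef = std::exp(-dt / p.ca_tau);
  for (int i = 0; i < p.n; ++i) {
    double influx = p.ca_gain * std::max(0.0, -ica[i]);   // per ms
    double target = influx * p.ca_tau;
    st.chi[i] = target + (st.chi[i] - target) * ef;
    if (st.chi[i] < 0.0) st.chi[i] = 0.0;
  }
  return dmax;
}

List state_list(const Packed& p, const State& st) {
  return List::create(_["v"] = NumericVector(st.v.begin(), st.v.end()),
                      _["m"] = NumericVector(st.m.begin(), st.m.end()),
                      _["chi"] = NumericVector(st.chi.begin(),
                                               st.chi.end()));
}

} // namespace

// [[Rcpp::export]]
List cpp_simulate(List pm, NumericMatrix sources, double duration,
                  double dt, int record_every, List init) {
  Packed p = unpack(pm);
  State st = init_state(p, init);
  std::vector<double> gtot(p.n), getot(p.n), iinj(p.n), diag(p.n),
      rhs(p.n), open((size_t)p.nchan * p.n), ica(p.n);

  int nsteps = (int)std::llround(duration / dt);
  int nrec = nsteps / record_every + 1;
  NumericMatrix V(nrec, p.n);
  NumericVector time(nrec);
  int r = 0;
  for (int i = 0; i < p.n; ++i) V(0, i) = st.v[i];
  time[0] = 0.0;
  r = 1;
  for (int k = 0; k < nsteps; ++k) {
    double t = k * dt;
    step(p, st, sources, t, dt, gtot, getot, iinj, diag, rhs, open, ica);
    for (int i = 0; i < p.n; ++i) {
      if (!std::isfinite(st.v[i]))
        stop("numeric blow-up in compartment %d near t = %.3f ms",
             i + 1, t + dt);
    }
    if ((k + 1) % record_every == 0 && r < nrec) {
      for (int i = 0; i < p.n; ++i) V(r, i) = st.v[i];
      time[r] = (k + 1) * dt;
      ++r;
    }
  }
  return List::create(_["time"] = time, _["v"] = V,
                      _["state"] = state_list(p, st));
}

// [[Rcpp::export]]
List cpp_relax(List pm, NumericMatrix sources, double max_ms, double dt,
               double tol, List init) {
  Packed p = unpack(pm);
  State st = init_state(p, init);
  std::vector<double> gtot(p.n), getot(p.n), iinj(p.n), diag(p.n),
      rhs(p.n), open((size_t)p.nchan * p.n), ica(p.n);
  int nsteps = (int)std::llround(max_ms / dt);
  bool converged = false;
  double t_end = max_ms;
  for (int k = 0; k < nsteps; ++k) {
    double dmax = step(p, st, sources, k * dt, dt, gtot, getot, iinj, diag,
                       rhs, open, ica);
    for (int i = 0; i < p.n; ++i)
      if (!std::isfinite(st.v[i]))
        stop("numeric blow-up in compartment %d near t = %.3f ms",
             i + 1, k * dt);
    if (dmax / dt < tol && k * dt > 50.0) {   // mV/ms rate criterion
      converged = true;
      t_end = (k + 1) * dt;
      break;
    }
  }
  return List::create(_["v"] = NumericVector(st.v.begin(), st.v.end()),
                      _["state"] = state_list(p, st),
                      _["converged"] = converged, _["t"] = t_end);
}
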