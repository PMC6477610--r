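#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step integrator for networks of non-spiking leaky-integrator neurons
// with a single persistent-sodium conductance and graded (piecewise-linear)
// synapses.  Unit system: mV / ms / nA / uS / nF (so G*V is nA and
// (nA)/(nF) is mV/ms without conversion factors).
//
// Per-step order of operations (documented in the package vignette):
//   1. external current = stimulus + noise + afferent current (plant state
//      at step start; exactly zero when no plant or zero gains)
//   2. neuron states advanced over dt (exponential Euler or RK4)
//   3. muscle activations and joint states advanced (semi-implicit Euler)
//      from the just-updated motoneuron voltages
//   4. afferent currents for the next step computed from the new plant state

static inline double zinf(double V, double A, double S, double E) {
  return 1.0 / (1.0 + A * std::exp(S * (V - E)));
}

static inline double syn_g(double Vpre, double gmax, double Elo, double Ehi) {
  if (Vpre <= Elo) return 0.0;
  if (Vpre >= Ehi) return gmax;
  return gmax * (Vpre - Elo) / (Ehi - Elo);
}

struct Net {
  int n;
  const double *C, *G, *Erest, *GNa, *ENa;
  const double *Am, *Sm, *Em, *taum, *Ah, *Sh, *Eh, *tauh;
  int ns;
  const int *pre, *post;
  const double *gmax, *Esyn, *Elo, *Ehi;
};

// dV/dt, dm/dt, dh/dt for the whole network given instantaneous state and
// per-neuron external current.  Used by the RK4 path.
static void rhs(const Net &net,
                const std::vector<double> &V, const std::vector<double> &m,
                const std::vector<double> &h, const std::vector<double> &Iext,
                std::vector<double> &dV, std::vector<double> &dm,
                std::vector<double> &dh) {
  const int n = net.n;
  std::vector<double> Isyn(n, 0.0);
  for (int s = 0; s < net.ns; ++s) {
    double g = syn_g(V[net.pre[s]], net.gmax[s], net.Elo[s], net.Ehi[s]);
    Isyn[net.post[s]] += g * (net.Esyn[s] - V[net.post[s]]);
  }
  for (int i = 0; i < n; ++i) {
    double ina = 0.0;
    if (net.GNa[i] > 0.0) {
      ina = net.GNa[i] * m[i] * h[i] * (net.ENa[i] - V[i]);
      dm[i] = (zinf(V[i], net.Am[i], net.Sm[i], net.Em[i]) - m[i]) / net.taum[i];
      dh[i] = (zinf(V[i], net.Ah[i], net.Sh[i], net.Eh[i]) - h[i]) / net.tauh[i];
    } else {
      dm[i] = 0.0;
      dh[i] = 0.0;
    }
    dV[i] = (net.G[i] * (net.Erest[i] - V[i]) + Isyn[i] + ina + Iext[i]) / net.C[i];
  }
}

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(List neurons, List synapses, List stimuli, List noise,
                 List plant, double dt, int n_steps, int record_every,
                 int method, bool record_gates) {
  NumericVector C_ = neurons["C"], G_ = neurons["G_leak"],
                Er_ = neurons["E_rest"], GNa_ = neurons["G_Na"],
                ENa_ = neurons["E_Na"], Am_ = neurons["m_A"],
                Sm_ = neurons["m_S"], Em_ = neurons["m_E"],
                tm_ = neurons["m_tau"], Ah_ = neurons["h_A"],
                Sh_ = neurons["h_S"], Eh_ = neurons["h_E"],
                th_ = neurons["h_tau"];
  const int n = C_.size();

  IntegerVector pre_ = synapses["pre"], post_ = synapses["post"];
  NumericVector gmax_ = synapses["g_max"], Es_ = synapses["E_syn"],
                El_ = synapses["E_lo"], Eh2_ = synapses["E_hi"];
  const int ns = pre_.size();

  Net net;
  net.n = n; net.ns = ns;
  net.C = REAL(C_); net.G = REAL(G_); net.Erest = REAL(Er_);
  net.GNa = REAL(GNa_); net.ENa = REAL(ENa_);
  net.Am = REAL(Am_); net.Sm = REAL(Sm_); net.Em = REAL(Em_); net.taum = REAL(tm_);
  net.Ah = REAL(Ah_); net.Sh = REAL(Sh_); net.Eh = REAL(Eh_); net.tauh = REAL(th_);
  net.pre = INTEGER(pre_); net.post = INTEGER(post_);
  net.gmax = REAL(gmax_); net.Esyn = REAL(Es_); net.Elo = REAL(El_);
  net.Ehi = REAL(Eh2_);

  IntegerVector st_t = stimuli["target"], st_on = stimuli["on_step"],
                st_off = stimuli["off_step"];
  NumericVector st_a = stimuli["amplitude"];
  const int nstim = st_t.size();

  IntegerVector nz_t = noise["target"];
  NumericVector nz_sd = noise["sd"];
  const int nnz = nz_t.size();
  const double sqrt_dt = std::sqrt(dt);

  // plant: optional list of joints; empty "joint_ext" means no plant
  IntegerVector pj_ext, pj_flx;
  NumericVector pj_inertia, pj_damping, pj_gain, pj_stiff, pj_ref,
                pj_act_tau, pj_act_lo, pj_act_hi;
  IntegerVector af_joint, af_type, af_target;
  NumericVector af_gain;
  double af_clamp = 0.0;
  int njt = 0, naf = 0;
  if (plant.size() > 0) {
    pj_ext = as<IntegerVector>(plant["mn_ext"]);
    pj_flx = as<IntegerVector>(plant["mn_flx"]);
    pj_inertia = as<NumericVector>(plant["inertia"]);
    pj_damping = as<NumericVector>(plant["damping"]);
    pj_gain = as<NumericVector>(plant["gain"]);
    pj_stiff = as<NumericVector>(plant["stiffness"]);
    pj_ref = as<NumericVector>(plant["angle_ref"]);
    pj_act_tau = as<NumericVector>(plant["act_tau"]);
    pj_act_lo = as<NumericVector>(plant["act_lo"]);
    pj_act_hi = as<NumericVector>(plant["act_hi"]);
    njt = pj_ext.size();
    af_joint = as<IntegerVector>(plant["aff_joint"]);
    af_type = as<IntegerVector>(plant["aff_type"]);     // 0 Ia, 1 II, 2 Ib
    af_target = as<IntegerVector>(plant["aff_target"]);
    af_gain = as<NumericVector>(plant["aff_gain"]);
    af_clamp = as<double>(plant["aff_clamp"]);
    naf = af_joint.size();
  }

  std::vector<double> V(n), m(n, 0.0), h(n, 0.0);
  {
    NumericVector V0 = neurons["V0"], m0 = neurons["m0"], h0 = neurons["h0"];
    for (int i = 0; i < n; ++i) { V[i] = V0[i]; m[i] = m0[i]; h[i] = h0[i]; }
  }
  std::vector<double> angle(njt, 0.0), vel(njt, 0.0),
                      act_e(njt, 0.0), act_f(njt, 0.0);
  if (njt > 0) {
    NumericVector a0 = plant["angle0"];
    for (int j = 0; j < njt; ++j) angle[j] = a0[j];
  }

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix Vout(n_rec, n);
  NumericMatrix mout(record_gates ? n_rec : 1, record_gates ? n : 1);
  NumericMatrix hout(record_gates ? n_rec : 1, record_gates ? n : 1);
  NumericMatrix plant_out(njt > 0 ? n_rec : 1, njt > 0 ? 4 * njt : 1);
  NumericVector tout(n_rec);

  std::vector<double> Iext(n), Iaff(n, 0.0);
  std::vector<double> dV(n), dm(n), dh(n);
  std::vector<double> k1V(n), k1m(n), k1h(n), k2V(n), k2m(n), k2h(n),
      k3V(n), k3m(n), k3h(n), k4V(n), k4m(n), k4h(n),
      tV(n), tm2(n), th2(n);

  int bad_neuron = -1;
  double bad_time = NA_REAL;
  std::string bad_what = "";

  RNGScope scope;

  int rec = 0;
  auto record = [&](int step) {
    double t = step * dt;
    tout[rec] = t;
    for (int i = 0; i < n; ++i) Vout(rec, i) = V[i];
    if (record_gates)
      for (int i = 0; i < n; ++i) { mout(rec, i) = m[i]; hout(rec, i) = h[i]; }
    if (njt > 0)
      for (int j = 0; j < njt; ++j) {
        plant_out(rec, 4 * j) = angle[j];
        plant_out(rec, 4 * j + 1) = vel[j];
        plant_out(rec, 4 * j + 2) = act_e[j];
        plant_out(rec, 4 * j + 3) = act_f[j];
      }
    ++rec;
  };
  record(0);

  for (int step = 0; step < n_steps; ++step) {
    // 1. external currents
    for (int i = 0; i < n; ++i) Iext[i] = Iaff[i];
    for (int s = 0; s < nstim; ++s)
      if (step >= st_on[s] && step < st_off[s]) Iext[st_t[s]] += st_a[s];
    for (int s = 0; s < nnz; ++s)
      Iext[nz_t[s]] += nz_sd[s] / sqrt_dt * norm_rand();

    // 2. neurons
    if (method == 0) {  // exponential Euler
      // synaptic conductances from voltages at step start
      std::vector<double> Gs(n, 0.0), GsE(n, 0.0);
      for (int s = 0; s < ns; ++s) {
        double g = syn_g(V[net.pre[s]], net.gmax[s], net.Elo[s], net.Ehi[s]);
        Gs[net.post[s]] += g;
        GsE[net.post[s]] += g * net.Esyn[s];
      }
      for (int i = 0; i < n; ++i) {
        if (net.GNa[i] > 0.0) {
          double mi = zinf(V[i], net.Am[i], net.Sm[i], net.Em[i]);
          double hi = zinf(V[i], net.Ah[i], net.Sh[i], net.Eh[i]);
          m[i] += (mi - m[i]) * (1.0 - std::exp(-dt / net.taum[i]));
          h[i] += (hi - h[i]) * (1.0 - std::exp(-dt / net.tauh[i]));
        }
        double gna = net.GNa[i] * m[i] * h[i];
        double A = net.G[i] + gna + Gs[i];
        double B = net.G[i] * net.Erest[i] + gna * net.ENa[i] + GsE[i] + Iext[i];
        double Vinf = B / A;
        V[i] = Vinf + (V[i] - Vinf) * std::exp(-A * dt / net.C[i]);
      }
    } else {  // classical RK4 on the full coupled system
      rhs(net, V, m, h, Iext, k1V, k1m, k1h);
      for (int i = 0; i < n; ++i) {
        tV[i] = V[i] + 0.5 * dt * k1V[i];
        tm2[i] = m[i] + 0.5 * dt * k1m[i];
        th2[i] = h[i] + 0.5 * dt * k1h[i];
      }
      rhs(net, tV, tm2, th2, Iext, k2V, k2m, k2h);
      for (int i = 0; i < n; ++i) {
        tV[i] = V[i] + 0.5 * dt * k2V[i];
        tm2[i] = m[i] + 0.5 * dt * k2m[i];
        th2[i] = h[i] + 0.5 * dt * k2h[i];
      }
      rhs(net, tV, tm2, th2, Iext, k3V, k3m, k3h);
      for (int i = 0; i < n; ++i) {
        tV[i] = V[i] + dt * k3V[i];
        tm2[i] = m[i] + dt * k3m[i];
        th2[i] = h[i] + dt * k3h[i];
      }
      rhs(net, tV, tm2, th2, Iext, k4V, k4m, k4h);
      for (int i = 0; i < n; ++i) {
        V[i] += dt / 6.0 * (k1V[i] + 2.0 * k2V[i] + 2.0 * k3V[i] + k4V[i]);
        m[i] += dt / 6.0 * (k1m[i] + 2.0 * k2m[i] + 2.0 * k3m[i] + k4m[i]);
        h[i] += dt / 6.0 * (k1h[i] + 2.0 * k2h[i] + 2.0 * k3h[i] + k4h[i]);
      }
    }

    // gate guard: clamp tiny overshoots, abort on larger excursions
    for (int i = 0; i < n && bad_neuron < 0; ++i) {
      if (net.GNa[i] <= 0.0) continue;
      if (m[i] < -1e-9 || m[i] > 1.0 + 1e-9 || h[i] < -1e-9 ||
          h[i] > 1.0 + 1e-9) {
        bad_neuron = i; bad_time = (step + 1) * dt; bad_what = "gate";
      } else {
        if (m[i] < 0.0) m[i] = 0.0; else if (m[i] > 1.0) m[i] = 1.0;
        if (h[i] < 0.0) h[i] = 0.0; else if (h[i] > 1.0) h[i] = 1.0;
      }
    }
    for (int i = 0; i < n && bad_neuron < 0; ++i)
      if (!std::isfinite(V[i]) || std::fabs(V[i]) > 500.0) {
        bad_neuron = i; bad_time = (step + 1) * dt; bad_what = "voltage";
      }
    if (bad_neuron >= 0) break;

    // 3. plant (semi-implicit Euler), from just-updated MN voltages
    for (int j = 0; j < njt; ++j) {
      double ue = (V[pj_ext[j]] - pj_act_lo[j]) / (pj_act_hi[j] - pj_act_lo[j]);
      double uf = (V[pj_flx[j]] - pj_act_lo[j]) / (pj_act_hi[j] - pj_act_lo[j]);
      ue = ue < 0.0 ? 0.0 : (ue > 1.0 ? 1.0 : ue);
      uf = uf < 0.0 ? 0.0 : (uf > 1.0 ? 1.0 : uf);
      act_e[j] += (ue - act_e[j]) * (1.0 - std::exp(-dt / pj_act_tau[j]));
      act_f[j] += (uf - act_f[j]) * (1.0 - std::exp(-dt / pj_act_tau[j]));
      double torque = pj_gain[j] * (act_e[j] - act_f[j]) -
                      pj_stiff[j] * (angle[j] - pj_ref[j]);
      vel[j] += dt * (torque - pj_damping[j] * vel[j]) / pj_inertia[j];
      angle[j] += dt * vel[j];  // semi-implicit: uses updated velocity
      if (!std::isfinite(angle[j]) || std::fabs(angle[j]) > 1e3) {
        bad_neuron = n + j; bad_time = (step + 1) * dt; bad_what = "plant";
      }
    }
    if (bad_neuron >= 0) break;

    // 4. afferent currents for the next step
    if (njt > 0) {
      std::fill(Iaff.begin(), Iaff.end(), 0.0);
      for (int a = 0; a < naf; ++a) {
        int j = af_joint[a];
        double sig;
        if (af_type[a] == 0) sig = vel[j];                       // Ia-like
        else if (af_type[a] == 1) sig = angle[j] - pj_ref[j];    // II-like
        else {                                                   // Ib-like
          double te = pj_gain[j] * act_e[j];
          sig = te > 0.0 ? te : 0.0;
        }
        double cur = af_gain[a] * sig;
        if (cur > af_clamp) cur = af_clamp;
        if (cur < -af_clamp) cur = -af_clamp;
        Iaff[af_target[a]] += cur;
      }
    }

    if ((step + 1) % record_every == 0) record(step + 1);
  }

  List out = List::create(
      _["ok"] = bad_neuron < 0, _["time"] = tout, _["V"] = Vout,
      _["m"] = mout, _["h"] = hout, _["plant"] = plant_out,
      _["n_recorded"] = rec, _["bad_neuron"] = bad_neuron + 1,
      _["bad_time"] = bad_time, _["bad_what"] = bad_what);
  return out;
}
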