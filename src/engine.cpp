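// Fixed-step network integrator for the six-layer thalamocortical model.
//
// Gating variables advance by exponential Euler using voltage-indexed
// lookup tables (steady state + per-step decay factor) built in R from
// the same rate functions exported to users; compartment voltages use a
// semi-implicit (conductance-implicit) update; the quasi-static
// axosomatic compartment of cortical cells is solved per step by damped
// Newton iteration with gating frozen.
//
// Synaptic open fractions are stored once per (projection, source cell)
// -- all fan-out targets of a source share the same presynaptic pulse
// train -- and the radius-based fan-in sums are computed with prefix
// sums over the contiguous source windows.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Table {
  std::vector<double> inf, dec;
  double vmin, vstep;
  int n;
  void load(const NumericMatrix& m, double vmin_, double vstep_) {
    n = m.nrow(); vmin = vmin_; vstep = vstep_;
    inf.resize(n); dec.resize(n);
    for (int i = 0; i < n; ++i) { inf[i] = m(i, 0); dec[i] = m(i, 1); }
  }
  inline void look(double v, double& xinf, double& xdec) const {
    double p = (v - vmin) / vstep;
    if (p < 0) p = 0;
    if (p > n - 1.001) p = n - 1.001;
    int i = (int)p;
    double f = p - i;
    xinf = inf[i] + (inf[i + 1] - inf[i]) * f;
    xdec = dec[i] + (dec[i + 1] - dec[i]) * f;
  }
  inline double look_inf(double v) const {
    double p = (v - vmin) / vstep;
    if (p < 0) p = 0;
    if (p > n - 1.001) p = n - 1.001;
    int i = (int)p;
    double f = p - i;
    return inf[i] + (inf[i + 1] - inf[i]) * f;
  }
};

inline double gate_adv(const Table& tb, double v, double x) {
  double xi, xd;
  tb.look(v, xi, xd);
  return xi + (x - xi) * xd;
}

struct Layer {
  std::string name;
  int size = 0;
  int kind = 0; // 0 cortical, 1 TC, 2 RE
  // shared
  double Cm = 1, area = 1;
  // cortical
  double rho = 1, gSD = 0, gDS = 0;
  double s_gNa = 0, s_ENa = 50, s_gK = 0, s_EK = -95, s_gNap = 0;
  double d_gNa = 0, d_gNap = 0, d_gKL = 0, d_EKL = -95, d_gL = 0,
         d_EL = -68, d_gHVA = 0, d_ECa = 140, d_gKCa = 0, d_gKm = 0,
         d_EK = -95;
  // thalamic
  double gNa = 0, ENa = 50, gK = 0, EK = -95, gKL = 0, EKL = -95,
         gL = 0, EL = -70, gT = 0, ECa = 120, gh = 0, Eh = -40;
  int MT = 2;             // T-current activation exponent
  double ca_tau = 5, ca_dec = 1, ca_Atau = 0;
  double kca_scale = 10; // KCa activation rate per mM of calcium
  double hetero = 0; // fractional uniform jitter of the leak conductance
  std::vector<double> leak_mul; // per-cell multiplier
  // state
  std::vector<double> VD, VS, V;
  std::vector<double> mnas, hnas, nks; // soma gates
  std::vector<double> mnad, hnad, mkm, mkca, mhva, hhva, ca; // dendrite
  std::vector<double> mna, hna, nk, mt, ht, oh; // thalamic
  std::vector<double> last_spike;
  // per-step synaptic accumulators (density units, mS/cm^2 and
  // mS/cm^2*mV) on the synaptic compartment (dendrite for cortical)
  std::vector<double> Gsyn, GEsyn;
  double inj_density = 0; // uA/cm^2, step protocol
  double syn_conv = 0;    // uS -> mS/cm^2 on the synaptic compartment
};

struct Projection {
  int src = 0, tgt = 0;
  int receptor = 0; // 0 AMPA, 1 NMDA, 2 GABA_A, 3 GABA_B
  double g = 0, E = 0, radius = 0;
  int delay_steps = 0;
  double delay_ms = 0;
  bool depressing = false;
  double U = 0;
  bool self_excl = false;
  bool fanin_div = false; // g is the total conductance per target cell
  // kinetics
  double alpha = 0, beta = 0;
  // per-source state
  std::vector<double> O, t0, D, last_pulse;
  std::vector<double> Rg, Gg; // GABA_B cascade
  std::vector<std::queue<double> > pend;
  // fan-in windows per target
  std::vector<int> ilo, ihi;
  std::vector<double> w, pref, inv_fanin;
  bool onto_py = false;
};

struct MiniStream {
  int tgt = 0;      // layer index
  int receptor = 0; // 0 AMPA, 2 GABA_A
  double g = 0, E = 0;
  double alpha = 0, beta = 0;
  std::vector<double> O, t0, next_t;
  bool onto_py = false;
};

inline double nap_minf(double v) { return 0.02 / (1 + exp(-(v + 42) / 5)); }

} // namespace

// [[Rcpp::export]]
List simulate_network_cpp(List cfg, List tables, double duration_ms,
                          double dt, List protocol) {
  const double vmin = as<double>(tables["vmin"]);
  const double vstep = as<double>(tables["vstep"]);
  Table T_cNa_m, T_cNa_h, T_cK, T_cKm, T_cHVA_m, T_cHVA_h,
      T_tNa_m, T_tNa_h, T_tK, T_tcT_m, T_tcT_h, T_reT_m, T_reT_h, T_ih;
  T_cNa_m.load(tables["cNa_m"], vmin, vstep);
  T_cNa_h.load(tables["cNa_h"], vmin, vstep);
  T_cK.load(tables["cK"], vmin, vstep);
  T_cKm.load(tables["cKm"], vmin, vstep);
  T_cHVA_m.load(tables["cHVA_m"], vmin, vstep);
  T_cHVA_h.load(tables["cHVA_h"], vmin, vstep);
  T_tNa_m.load(tables["tNa_m"], vmin, vstep);
  T_tNa_h.load(tables["tNa_h"], vmin, vstep);
  T_tK.load(tables["tK"], vmin, vstep);
  T_tcT_m.load(tables["tcT_m"], vmin, vstep);
  T_tcT_h.load(tables["tcT_h"], vmin, vstep);
  T_reT_m.load(tables["reT_m"], vmin, vstep);
  T_reT_h.load(tables["reT_h"], vmin, vstep);
  T_ih.load(tables["ih"], vmin, vstep);
  NumericVector nmdaF = tables["nmdaF"]; // f(V) on the same grid
  const int nF = nmdaF.size();
  auto nmda_f = [&](double v) {
    double p = (v - vmin) / vstep;
    if (p < 0) p = 0;
    if (p > nF - 1.001) p = nF - 1.001;
    int i = (int)p;
    double f = p - i;
    return nmdaF[i] + (nmdaF[i + 1] - nmdaF[i]) * f;
  };
  // GHK driving function for the thalamic T current (normalized to the
  // linear drive at -60 mV with E_Ca = 120)
  NumericVector tdrive = tables["tdrive"];
  auto t_drive = [&](double v) {
    double p = (v - vmin) / vstep;
    if (p < 0) p = 0;
    if (p > nF - 1.001) p = nF - 1.001;
    int i = (int)p;
    double f = p - i;
    return tdrive[i] + (tdrive[i + 1] - tdrive[i]) * f;
  };

  // calcium pool constants (per-layer relaxation time)
  const double ca_inf = 2.4e-4, ca_A = 5.1819e-5;
  const double QT = 2.9529;

  // --- layers ---
  List Lcfg = cfg["layers"];
  int nL = Lcfg.size();
  std::vector<Layer> lay(nL);
  int py_idx = -1;
  for (int l = 0; l < nL; ++l) {
    List lc = Lcfg[l];
    Layer& L = lay[l];
    L.name = as<std::string>(lc["name"]);
    L.size = as<int>(lc["size"]);
    L.kind = as<int>(lc["kind"]);
    List p = lc["params"];
    L.ca_tau = as<double>(p["ca_tau"]);
    L.ca_dec = exp(-dt / L.ca_tau);
    L.ca_Atau = ca_A * L.ca_tau;
    L.hetero = p.containsElementNamed("hetero") ? as<double>(p["hetero"]) : 0.0;
    L.leak_mul.assign(as<int>(lc["size"]), 1.0);
    if (L.hetero > 0)
      for (size_t i = 0; i < L.leak_mul.size(); ++i)
        L.leak_mul[i] = 1.0 + L.hetero * (2.0 * unif_rand() - 1.0);
    if (L.kind == 0) {
      L.Cm = as<double>(p["Cm"]);
      L.rho = as<double>(p["rho"]);
      double R_ohm = as<double>(p["R_Mohm"]) * 1e6;
      double S = as<double>(p["S_soma"]);
      L.gDS = 1.0 / (R_ohm * S) * 1000.0;        // mS/cm^2 (soma-referred)
      L.gSD = L.gDS / L.rho;                     // dendrite-referred
      L.area = L.rho * S;                        // synaptic compartment
      List so = p["soma"], de = p["dend"];
      L.s_gNa = as<double>(so["g_Na"]); L.s_ENa = as<double>(so["E_Na"]);
      L.s_gK = as<double>(so["g_K"]); L.s_EK = as<double>(so["E_K"]);
      L.s_gNap = as<double>(so["g_Nap"]);
      L.d_gNa = as<double>(de["g_Na"]); L.d_gNap = as<double>(de["g_Nap"]);
      L.d_gKL = as<double>(de["g_KL"]); L.d_EKL = as<double>(de["E_KL"]);
      L.d_gL = as<double>(de["g_L"]); L.d_EL = as<double>(de["E_L"]);
      L.d_gHVA = as<double>(de["g_HVA"]); L.d_ECa = as<double>(de["E_Ca"]);
      L.d_gKCa = as<double>(de["g_KCa"]); L.d_gKm = as<double>(de["g_Km"]);
      L.d_EK = as<double>(de["E_K"]);
      if (de.containsElementNamed("kca_per_mM"))
        L.kca_scale = as<double>(de["kca_per_mM"]);
      if (L.name == "PY") py_idx = l;
    } else {
      L.Cm = as<double>(p["Cm"]);
      L.area = as<double>(p["area"]);
      L.gNa = as<double>(p["g_Na"]); L.ENa = as<double>(p["E_Na"]);
      L.gK = as<double>(p["g_K"]); L.EK = as<double>(p["E_K"]);
      L.gKL = as<double>(p["g_KL"]); L.EKL = as<double>(p["E_KL"]);
      L.gL = as<double>(p["g_L"]); L.EL = as<double>(p["E_L"]);
      L.gT = as<double>(p["g_T"]); L.ECa = as<double>(p["E_Ca"]);
      L.MT = as<int>(p["M_T"]);
      if (L.kind == 1) { L.gh = as<double>(p["g_h"]); L.Eh = as<double>(p["E_h"]); }
    }
    L.syn_conv = 1e-3 / L.area;
    int n = L.size;
    L.last_spike.assign(n, -1e30);
    L.Gsyn.assign(n, 0.0);
    L.GEsyn.assign(n, 0.0);
    if (L.kind == 0) {
      double v0 = L.d_EL;
      L.VD.assign(n, v0); L.VS.assign(n, v0);
      double xi, xd;
      T_cNa_m.look(v0, xi, xd); L.mnas.assign(n, xi); L.mnad.assign(n, xi);
      T_cNa_h.look(v0, xi, xd); L.hnas.assign(n, xi); L.hnad.assign(n, xi);
      T_cK.look(v0, xi, xd); L.nks.assign(n, xi);
      T_cKm.look(v0, xi, xd); L.mkm.assign(n, xi);
      T_cHVA_m.look(v0, xi, xd); L.mhva.assign(n, xi);
      T_cHVA_h.look(v0, xi, xd); L.hhva.assign(n, xi);
      double a0 = 10.0 * ca_inf; // init at the default scale
      L.mkca.assign(n, a0 / (a0 + 0.02));
      L.ca.assign(n, ca_inf);
    } else {
      double v0 = L.EL;
      L.V.assign(n, v0);
      double xi, xd;
      T_tNa_m.look(v0, xi, xd); L.mna.assign(n, xi);
      T_tNa_h.look(v0, xi, xd); L.hna.assign(n, xi);
      T_tK.look(v0, xi, xd); L.nk.assign(n, xi);
      // T-current inactivation starts at zero (fully inactivated):
      // steady-state initialization at E_L fires a spurious rebound
      // burst at t = 0 that can kick the self-exciting spindle loop
      if (L.kind == 1) {
        T_tcT_m.look(v0, xi, xd); L.mt.assign(n, xi);
        L.ht.assign(n, 0.0);
        L.oh.assign(n, T_ih.look_inf(v0));
      } else {
        T_reT_m.look(v0, xi, xd); L.mt.assign(n, xi);
        L.ht.assign(n, 0.0);
      }
      L.ca.assign(n, ca_inf);
    }
  }

  // --- synaptic constants ---
  List rec = cfg["receptors"];
  List rAMPA = rec["AMPA"], rNMDA = rec["NMDA"], rGA = rec["GABA_A"],
       rGB = rec["GABA_B"];
  double al[3] = {as<double>(rAMPA["alpha"]), as<double>(rNMDA["alpha"]),
                  as<double>(rGA["alpha"])};
  double be[3] = {as<double>(rAMPA["beta"]), as<double>(rNMDA["beta"]),
                  as<double>(rGA["beta"])};
  double Edef[4] = {as<double>(rAMPA["E"]), as<double>(rNMDA["E"]),
                    as<double>(rGA["E"]), as<double>(rGB["E"])};
  const double K1 = as<double>(rGB["K1"]), K2 = as<double>(rGB["K2"]),
               K3 = as<double>(rGB["K3"]), K4 = as<double>(rGB["K4"]),
               Khill = as<double>(rGB["K_hill"]);
  List trans = cfg["transmitter"];
  const double pulse_A = as<double>(trans["A"]);
  const double t_max = as<double>(trans["t_max"]);
  List dep = cfg["depression"];
  const double tau_rec = as<double>(dep["tau_rec"]);

  // --- projections ---
  List Pcfg = cfg["projections"];
  int nP = Pcfg.size();
  std::vector<Projection> proj(nP);
  for (int k = 0; k < nP; ++k) {
    List pc = Pcfg[k];
    Projection& P = proj[k];
    P.src = as<int>(pc["src"]);
    P.tgt = as<int>(pc["tgt"]);
    P.receptor = as<int>(pc["receptor"]);
    P.g = as<double>(pc["g"]);
    P.E = as<double>(pc["E"]);
    P.radius = as<double>(pc["radius"]);
    P.delay_ms = as<double>(pc["delay_ms"]);
    P.delay_steps = (int)std::lround(P.delay_ms / dt);
    P.depressing = as<bool>(pc["depressing"]);
    P.U = as<double>(pc["U"]);
    P.self_excl = as<bool>(pc["self_excl"]);
    P.fanin_div = as<bool>(pc["fanin_div"]);
    P.onto_py = (P.tgt == py_idx);
    int ns = lay[P.src].size, nt = lay[P.tgt].size;
    P.O.assign(ns, 0.0);
    P.t0.assign(ns, -1e30);
    P.D.assign(ns, 1.0);
    P.last_pulse.assign(ns, -1e30);
    if (P.receptor == 3) { P.Rg.assign(ns, 0.0); P.Gg.assign(ns, 0.0); }
    if (P.delay_steps > 0) P.pend.assign(ns, std::queue<double>());
    if (P.receptor < 3) { P.alpha = al[P.receptor]; P.beta = be[P.receptor]; }
    P.w.assign(ns, 0.0);
    P.pref.assign(ns + 1, 0.0);
    P.ilo.assign(nt, 0); P.ihi.assign(nt, -1);
    for (int j = 0; j < nt; ++j) {
      double lo = (j - P.radius) * (double)ns / nt;
      double hi = (j + P.radius) * (double)ns / nt;
      int a = (int)std::ceil(lo - 1e-9), b = (int)std::floor(hi + 1e-9);
      if (a < 0) a = 0;
      if (b > ns - 1) b = ns - 1;
      P.ilo[j] = a; P.ihi[j] = b;
    }
    P.inv_fanin.assign(nt, 1.0);
    for (int j = 0; j < nt; ++j) {
      int nin = P.ihi[j] - P.ilo[j] + 1;
      if (P.self_excl && j >= P.ilo[j] && j <= P.ihi[j]) nin -= 1;
      if (P.fanin_div && nin > 0) P.inv_fanin[j] = 1.0 / nin;
    }
  }

  // receptor decay factors per full off-step
  double off_dec[3];
  for (int r = 0; r < 3; ++r) off_dec[r] = exp(-be[r] * dt);
  const double gb_R_dec = exp(-K2 * dt), gb_G_dec = exp(-K4 * dt);

  // --- minis ---
  List mcfg = cfg["minis"];
  bool minis_on = as<bool>(mcfg["enabled"]);
  double mini_rate_ms = as<double>(mcfg["rate_ms"]); // per target, gated
  double gate_delay = as<double>(mcfg["gate_delay_ms"]);
  std::vector<MiniStream> minis;
  if (minis_on) {
    List streams = mcfg["streams"];
    for (int s = 0; s < streams.size(); ++s) {
      List sc = streams[s];
      MiniStream M;
      M.tgt = as<int>(sc["tgt"]);
      M.receptor = as<int>(sc["receptor"]);
      M.g = as<double>(sc["g"]);
      M.E = Edef[M.receptor];
      M.alpha = al[M.receptor]; M.beta = be[M.receptor];
      int nt = lay[M.tgt].size;
      M.O.assign(nt, 0.0);
      M.t0.assign(nt, -1e30);
      M.next_t.assign(nt, R_PosInf);
      M.onto_py = (M.tgt == py_idx);
      minis.push_back(M);
    }
  }

  // --- spike / state-machine config ---
  List spk = cfg["spike"];
  const double v_th = as<double>(spk["threshold"]);
  const double refrac = as<double>(spk["refractory_ms"]);
  List sod = cfg["so_detect"];
  const double rate_up = as<double>(sod["rate_up"]);
  const double rate_down = as<double>(sod["rate_down"]);
  const int win_bins = (int)as<double>(sod["window_ms"]);
  const double down_hold = as<double>(sod["down_hold_ms"]);

  // --- protocol ---
  std::string pkind = as<std::string>(protocol["kind"]);
  double step_tc = 0, step_re = 0, step_on = 0, step_period = 1e30,
         step_start = 0;
  if (pkind == "step") {
    step_tc = as<double>(protocol["tc_nA"]);
    step_re = as<double>(protocol["re_nA"]);
    step_on = as<double>(protocol["on_ms"]);
    step_period = as<double>(protocol["period_ms"]);
    step_start = as<double>(protocol["start_ms"]);
  }

  // --- recording ---
  const double sample_ms = as<double>(cfg["sample_ms"]);
  const int sps = (int)std::lround(sample_ms / dt);
  const long nsteps = (long)std::lround(duration_ms / dt);
  const int nsamp = (int)(nsteps / sps);
  IntegerVector rec_layer = cfg["record_layer"];
  IntegerVector rec_cell = cfg["record_cell"];
  const int nrec = rec_layer.size();
  NumericMatrix Vrec(nsamp, nrec);
  NumericMatrix lfp(nsamp, 3); // AMPA, NMDA, GABA_A summed currents (nA)
  NumericVector samp_t(nsamp);
  IntegerVector samp_gate(nsamp), samp_state(nsamp);
  std::vector<int> spike_layer_v; std::vector<int> spike_cell_v;
  std::vector<double> spike_t_v;
  spike_layer_v.reserve(1 << 20);
  spike_cell_v.reserve(1 << 20);
  spike_t_v.reserve(1 << 20);
  std::vector<double> mini_times;
  std::vector<double> up_onsets, down_onsets, gate_opens, gate_closes;

  // SO state machine
  bool state_up = false;       // start in a down state
  bool gate_open = false;
  double down_onset_t = 0.0, below_since = -1.0, gate_open_at = gate_delay;
  std::vector<int> rate_ring(win_bins, 0);
  int ring_pos = 0, ring_sum = 0, bin_count = 0;
  int npy = (py_idx >= 0) ? lay[py_idx].size : 0;

  auto gate_draw_all = [&](double tnow) {
    for (size_t s = 0; s < minis.size(); ++s)
      for (size_t j = 0; j < minis[s].next_t.size(); ++j)
        minis[s].next_t[j] = tnow + R::exp_rand() / mini_rate_ms;
  };

  auto apply_pulse = [&](Projection& P, int i, double tstart) {
    if (P.depressing && P.last_pulse[i] > -1e29) {
      double d = tstart - P.last_pulse[i];
      if (d > 0)
        P.D[i] = 1.0 - (1.0 - P.D[i] * (1.0 - P.U)) * exp(-d / tau_rec);
    }
    P.last_pulse[i] = tstart;
    P.t0[i] = tstart;
  };

  double lfp_acc[3];

  for (long step = 0; step < nsteps; ++step) {
    double t = step * dt, tn = t + dt;
    bool record_now = ((step + 1) % sps == 0);
    lfp_acc[0] = lfp_acc[1] = lfp_acc[2] = 0.0;

    // ---- deliver delayed events, advance synaptic states ----
    for (int k = 0; k < nP; ++k) {
      Projection& P = proj[k];
      if (P.g == 0.0 && P.receptor != 3) {
        // still advance decay cheaply so re-enabling mid-run is sane
      }
      int ns = lay[P.src].size;
      if (P.delay_steps > 0) {
        for (int i = 0; i < ns; ++i) {
          std::queue<double>& q = P.pend[i];
          while (!q.empty() && q.front() <= t + 1e-9) {
            apply_pulse(P, i, q.front());
            q.pop();
          }
        }
      }
      if (P.receptor < 3) {
        double a = P.alpha, b = P.beta;
        double r_on = a * pulse_A + b, Oinf = a * pulse_A / r_on;
        for (int i = 0; i < ns; ++i) {
          double p0 = P.t0[i], p1 = P.t0[i] + t_max;
          double d_on = std::min(tn, p1) - std::max(t, p0);
          if (d_on > 0) {
            if (d_on > dt) d_on = dt;
            double O = P.O[i];
            O = Oinf + (O - Oinf) * exp(-r_on * d_on);
            double d_off = dt - d_on;
            if (d_off > 0) O *= exp(-b * d_off);
            P.O[i] = O;
          } else {
            P.O[i] *= off_dec[P.receptor];
          }
        }
      } else {
        for (int i = 0; i < ns; ++i) {
          double p0 = P.t0[i], p1 = P.t0[i] + t_max;
          double d_on = std::min(tn, p1) - std::max(t, p0);
          double R = P.Rg[i];
          if (d_on > 0) {
            if (d_on > dt) d_on = dt;
            double a_on = K1 * pulse_A + K2, Rinf = K1 * pulse_A / a_on;
            R = Rinf + (R - Rinf) * exp(-a_on * d_on);
            double d_off = dt - d_on;
            if (d_off > 0) R *= exp(-K2 * d_off);
          } else {
            R *= gb_R_dec;
          }
          P.Rg[i] = R;
          double Ginf = K3 * R / K4;
          P.Gg[i] = Ginf + (P.Gg[i] - Ginf) * gb_G_dec;
        }
      }
      // weights + prefix sums
      if (P.receptor == 3) {
        for (int i = 0; i < ns; ++i) {
          double G = P.Gg[i], G4 = G * G * G * G;
          P.w[i] = P.g * G4 / (G4 + Khill);
        }
      } else if (P.depressing) {
        for (int i = 0; i < ns; ++i) P.w[i] = P.g * P.D[i] * P.O[i];
      } else {
        for (int i = 0; i < ns; ++i) P.w[i] = P.g * P.O[i];
      }
      double acc = 0;
      P.pref[0] = 0;
      for (int i = 0; i < ns; ++i) { acc += P.w[i]; P.pref[i + 1] = acc; }
    }

    // ---- mini streams ----
    if (minis_on) {
      for (size_t s = 0; s < minis.size(); ++s) {
        MiniStream& M = minis[s];
        int nt = lay[M.tgt].size;
        if (gate_open && mini_rate_ms > 0) {
          for (int j = 0; j < nt; ++j) {
            while (M.next_t[j] <= t) {
              M.t0[j] = M.next_t[j];
              mini_times.push_back(M.next_t[j]);
              M.next_t[j] += R::exp_rand() / mini_rate_ms;
            }
          }
        }
        double a = M.alpha, b = M.beta;
        double r_on = a * pulse_A + b, Oinf = a * pulse_A / r_on;
        for (int j = 0; j < nt; ++j) {
          double p0 = M.t0[j], p1 = M.t0[j] + t_max;
          double d_on = std::min(tn, p1) - std::max(t, p0);
          if (d_on > 0) {
            if (d_on > dt) d_on = dt;
            double O = M.O[j];
            O = Oinf + (O - Oinf) * exp(-r_on * d_on);
            double d_off = dt - d_on;
            if (d_off > 0) O *= exp(-b * d_off);
            M.O[j] = O;
          } else {
            M.O[j] *= off_dec[M.receptor];
          }
        }
      }
    }

    // ---- accumulate synaptic conductances per target ----
    for (int l = 0; l < nL; ++l) {
      std::fill(lay[l].Gsyn.begin(), lay[l].Gsyn.end(), 0.0);
      std::fill(lay[l].GEsyn.begin(), lay[l].GEsyn.end(), 0.0);
    }
    for (int k = 0; k < nP; ++k) {
      Projection& P = proj[k];
      Layer& Lt = lay[P.tgt];
      int nt = Lt.size;
      bool same = P.self_excl;
      const double conv = Lt.syn_conv; // uS -> mS/cm^2
      for (int j = 0; j < nt; ++j) {
        double W = P.pref[P.ihi[j] + 1] - P.pref[P.ilo[j]];
        if (same && j >= P.ilo[j] && j <= P.ihi[j]) W -= P.w[j];
        if (W == 0.0) continue;
        W *= P.inv_fanin[j];
        double vpost = (Lt.kind == 0) ? Lt.VD[j] : Lt.V[j];
        double geff = W;
        if (P.receptor == 1) geff *= nmda_f(vpost);
        Lt.Gsyn[j] += geff * conv;
        Lt.GEsyn[j] += geff * conv * P.E;
        if (record_now && P.onto_py && P.receptor < 3)
          lfp_acc[P.receptor] += geff * (vpost - P.E); // nA
      }
    }
    if (minis_on) {
      for (size_t s = 0; s < minis.size(); ++s) {
        MiniStream& M = minis[s];
        Layer& Lt = lay[M.tgt];
        int nt = Lt.size;
        const double conv = Lt.syn_conv;
        int rrec = (M.receptor == 2) ? 2 : 0;
        for (int j = 0; j < nt; ++j) {
          double geff = M.g * M.O[j];
          if (geff == 0.0) continue;
          double vpost = (Lt.kind == 0) ? Lt.VD[j] : Lt.V[j];
          Lt.Gsyn[j] += geff * conv;
          Lt.GEsyn[j] += geff * conv * M.E;
          if (record_now && M.onto_py)
            lfp_acc[rrec] += geff * (vpost - M.E);
        }
      }
    }

    // ---- advance cells ----
    bool stim_on = false;
    if (pkind == "step" && t >= step_start) {
      double q = (t - step_start) / step_period;
      double ph = (q - std::floor(q)) * step_period;
      stim_on = (ph < step_on);
    }
    int pybin_spikes = 0;
    for (int l = 0; l < nL; ++l) {
      Layer& L = lay[l];
      int n = L.size;
      if (L.kind == 0) {
        const double cdt = L.Cm / dt;
        for (int i = 0; i < n; ++i) {
          double vd = L.VD[i], vs = L.VS[i];
          // gating (dendrite at VD, soma at VS)
          L.mnad[i] = gate_adv(T_cNa_m, vd, L.mnad[i]);
          L.hnad[i] = gate_adv(T_cNa_h, vd, L.hnad[i]);
          L.mkm[i] = gate_adv(T_cKm, vd, L.mkm[i]);
          L.mhva[i] = gate_adv(T_cHVA_m, vd, L.mhva[i]);
          L.hhva[i] = gate_adv(T_cHVA_h, vd, L.hhva[i]);
          L.mnas[i] = gate_adv(T_cNa_m, vs, L.mnas[i]);
          L.hnas[i] = gate_adv(T_cNa_h, vs, L.hnas[i]);
          L.nks[i] = gate_adv(T_cK, vs, L.nks[i]);
          // KCa: rates from [Ca] (scale calibrated; ca is in mM)
          double aK = L.kca_scale * L.ca[i], rK = (aK + 0.02) * QT;
          double mkinf = aK / (aK + 0.02);
          L.mkca[i] = mkinf + (L.mkca[i] - mkinf) * exp(-dt * rK);
          // calcium pool from I_HVA
          double m2 = L.mhva[i] * L.mhva[i];
          double ihva = L.d_gHVA * m2 * L.hhva[i] * (vd - L.d_ECa);
          double ca_t = ca_inf - L.ca_Atau * ihva;
          L.ca[i] = ca_t + (L.ca[i] - ca_t) * L.ca_dec;
          // dendrite semi-implicit update
          double m3h = L.mnad[i] * L.mnad[i] * L.mnad[i] * L.hnad[i];
          double mnap = nap_minf(vd);
          double gL_i = L.d_gL * L.leak_mul[i];
          double G = gL_i + L.d_gKL + L.d_gNa * m3h + L.d_gNap * mnap +
                     L.d_gKm * L.mkm[i] + L.d_gKCa * L.mkca[i] +
                     L.d_gHVA * m2 * L.hhva[i] + L.gSD + L.Gsyn[i];
          double GE = gL_i * L.d_EL + L.d_gKL * L.d_EKL +
                      (L.d_gNa * m3h + L.d_gNap * mnap) * L.s_ENa +
                      (L.d_gKm * L.mkm[i] + L.d_gKCa * L.mkca[i]) * L.d_EK +
                      L.d_gHVA * m2 * L.hhva[i] * L.d_ECa +
                      L.gSD * vs + L.GEsyn[i];
          double vd_new = (cdt * vd + GE + L.inj_density) / (cdt + G);
          // soma: damped Newton on the algebraic constraint
          double sm3h = L.mnas[i] * L.mnas[i] * L.mnas[i] * L.hnas[i];
          double x = vs;
          bool ok = false;
          for (int it = 0; it < 50; ++it) {
            double mn = nap_minf(x);
            double f = L.gDS * (vd_new - x) -
                       L.s_gNa * sm3h * (x - L.s_ENa) -
                       L.s_gNap * mn * (x - L.s_ENa) -
                       L.s_gK * L.nks[i] * (x - L.s_EK);
            double dmn = mn * (1.0 - mn / 0.02) / 5.0;
            double fp = -L.gDS - L.s_gNa * sm3h - L.s_gK * L.nks[i] -
                        L.s_gNap * (mn + dmn * (x - L.s_ENa));
            double dx = f / fp;
            if (dx > 20) dx = 20;
            if (dx < -20) dx = -20;
            x -= dx;
            if (std::fabs(dx) < 1e-6) { ok = true; break; }
          }
          if (!ok) stop("somatic constraint solve failed (layer %s, cell %d, t=%.2f ms)",
                        L.name.c_str(), i, t);
          double vs_new = x;
          // spike detection on the axosomatic compartment
          if (vs < v_th && vs_new >= v_th && tn - L.last_spike[i] >= refrac) {
            L.last_spike[i] = tn;
            spike_layer_v.push_back(l);
            spike_cell_v.push_back(i);
            spike_t_v.push_back(tn);
            if (l == py_idx) ++pybin_spikes;
            for (int k2 = 0; k2 < nP; ++k2) {
              Projection& P = proj[k2];
              if (P.src != l) continue;
              if (P.delay_steps > 0) P.pend[i].push(tn + P.delay_ms);
              else apply_pulse(P, i, tn);
            }
          }
          L.VD[i] = vd_new;
          L.VS[i] = vs_new;
        }
      } else {
        const double cdt = L.Cm / dt;
        double inj = 0;
        if (stim_on)
          inj = ((L.kind == 1) ? step_tc : step_re) * 1e-3 / L.area;
        for (int i = 0; i < n; ++i) {
          double v = L.V[i];
          L.mna[i] = gate_adv(T_tNa_m, v, L.mna[i]);
          L.hna[i] = gate_adv(T_tNa_h, v, L.hna[i]);
          L.nk[i] = gate_adv(T_tK, v, L.nk[i]);
          double it_g;
          if (L.kind == 1) {
            L.mt[i] = gate_adv(T_tcT_m, v, L.mt[i]);
            L.ht[i] = gate_adv(T_tcT_h, v, L.ht[i]);
            L.oh[i] = gate_adv(T_ih, v, L.oh[i]);
          } else {
            L.mt[i] = gate_adv(T_reT_m, v, L.mt[i]);
            L.ht[i] = gate_adv(T_reT_h, v, L.ht[i]);
          }
          double mM = L.mt[i];
          for (int e = 1; e < L.MT; ++e) mM *= L.mt[i];
          it_g = L.gT * mM * L.ht[i];
          // GHK drive, rescaled if the configured E_Ca differs from 120
          double drv = t_drive(v) * (-60.0 - L.ECa) / (-180.0);
          double i_t = it_g * drv;
          double E_eff = v - drv; // ohmic equivalent for the implicit update
          double ca_t = ca_inf - L.ca_Atau * i_t;
          L.ca[i] = ca_t + (L.ca[i] - ca_t) * L.ca_dec;
          double m3h = L.mna[i] * L.mna[i] * L.mna[i] * L.hna[i];
          double n4 = L.nk[i] * L.nk[i] * L.nk[i] * L.nk[i];
          double gKL_i = L.gKL * L.leak_mul[i];
          double G = L.gL + gKL_i + L.gNa * m3h + L.gK * n4 + it_g + L.Gsyn[i];
          double GE = L.gL * L.EL + gKL_i * L.EKL + L.gNa * m3h * L.ENa +
                      L.gK * n4 * L.EK + it_g * E_eff + L.GEsyn[i];
          if (L.kind == 1) {
            G += L.gh * L.oh[i];
            GE += L.gh * L.oh[i] * L.Eh;
          }
          double v_new = (cdt * v + GE + inj) / (cdt + G);
          if (v < v_th && v_new >= v_th && tn - L.last_spike[i] >= refrac) {
            L.last_spike[i] = tn;
            spike_layer_v.push_back(l);
            spike_cell_v.push_back(i);
            spike_t_v.push_back(tn);
            for (int k2 = 0; k2 < nP; ++k2) {
              Projection& P = proj[k2];
              if (P.src != l) continue;
              if (P.delay_steps > 0) P.pend[i].push(tn + P.delay_ms);
              else apply_pulse(P, i, tn);
            }
          }
          L.V[i] = v_new;
        }
      }
    }

    // ---- SO state machine on PY population rate (1 ms bins) ----
    bin_count += pybin_spikes;
    if ((step + 1) % (int)std::lround(1.0 / dt) == 0 && npy > 0) {
      ring_sum += bin_count - rate_ring[ring_pos];
      rate_ring[ring_pos] = bin_count;
      ring_pos = (ring_pos + 1) % win_bins;
      bin_count = 0;
      double rate_hz = ring_sum / (win_bins * 1e-3) / npy;
      if (!state_up) {
        if (rate_hz > rate_up) {
          state_up = true;
          up_onsets.push_back(tn);
          if (gate_open) { gate_open = false; gate_closes.push_back(tn); }
          gate_open_at = R_PosInf;
        } else if (!gate_open && tn >= gate_open_at) {
          gate_open = true;
          gate_opens.push_back(tn);
          gate_draw_all(tn);
        }
      } else {
        if (rate_hz < rate_down) {
          if (below_since < 0) below_since = tn;
          if (tn - below_since >= down_hold) {
            state_up = false;
            down_onset_t = below_since;
            down_onsets.push_back(down_onset_t);
            gate_open_at = down_onset_t + gate_delay;
            below_since = -1.0;
            if (tn >= gate_open_at) {
              gate_open = true;
              gate_opens.push_back(tn);
              gate_draw_all(tn);
            }
          }
        } else {
          below_since = -1.0;
        }
      }
      // gate may open mid-down-state
      if (!state_up && !gate_open && tn >= gate_open_at && npy > 0) {
        gate_open = true;
        gate_opens.push_back(tn);
        gate_draw_all(tn);
      }
    }

    // ---- record ----
    if (record_now) {
      int s = (int)((step + 1) / sps) - 1;
      if (s >= 0 && s < nsamp) {
        samp_t[s] = tn;
        lfp(s, 0) = lfp_acc[0];
        lfp(s, 1) = lfp_acc[1];
        lfp(s, 2) = lfp_acc[2];
        samp_gate[s] = gate_open ? 1 : 0;
        samp_state[s] = state_up ? 1 : 0;
        for (int r = 0; r < nrec; ++r) {
          Layer& L = lay[rec_layer[r]];
          double v = (L.kind == 0) ? L.VS[rec_cell[r]] : L.V[rec_cell[r]];
          Vrec(s, r) = v;
          if (!std::isfinite(v) || std::fabs(v) > 200)
            stop("numerical blow-up: layer %s cell %d at t=%.2f ms",
                 L.name.c_str(), (int)rec_cell[r], tn);
        }
      }
    }
  }

  // synapse instance count (consistency check against the R edge list)
  double syn_count = 0;
  for (int k = 0; k < nP; ++k) {
    Projection& P = proj[k];
    int nt = lay[P.tgt].size;
    for (int j = 0; j < nt; ++j) {
      if (P.ihi[j] < P.ilo[j]) continue;
      syn_count += P.ihi[j] - P.ilo[j] + 1;
      if (P.self_excl && j >= P.ilo[j] && j <= P.ihi[j]) syn_count -= 1;
    }
  }

  return List::create(
      _["time"] = samp_t,
      _["v"] = Vrec,
      _["lfp_components"] = lfp,
      _["gate"] = samp_gate,
      _["state_up"] = samp_state,
      _["spike_layer"] = wrap(spike_layer_v),
      _["spike_cell"] = wrap(spike_cell_v),
      _["spike_t"] = wrap(spike_t_v),
      _["mini_times"] = wrap(mini_times),
      _["up_onsets"] = wrap(up_onsets),
      _["down_onsets"] = wrap(down_onsets),
      _["gate_opens"] = wrap(gate_opens),
      _["gate_closes"] = wrap(gate_closes),
      _["n_synapses"] = syn_count);
}
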