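#include <Rcpp.h>
using namespace Rcpp;

// Single-compartment conductance-based neuron, fixed-step RK4.
//
// State: V (mV), m, h, n (fast Na / delayed-rectifier K gates),
// z (slow adaptation K gate), r (HCN gate), a, b (A-type gates).
// Conductances in nS, capacitance in pF, currents in pA, time in ms
// internally (pA/pF == mV/ms).

struct Params {
  double C, gL, EL, gNa, ENa, gK, EK, naShift;
  double gKir, vhKir, kKir;
  double gHCN, EH, tauHCN, vhHCN, kHCN;
  double gA, tauA, tauB;
  double gAdapt, tauAdapt;
};

static inline double safe_exp_ratio(double x, double denom) {
  // x / (1 - exp(-x/denom)) with the removable singularity at x = 0
  double e = x / denom;
  if (std::fabs(e) < 1e-7) return denom;
  return x / (1.0 - std::exp(-e));
}

static inline double am(double V) { return 0.1 * safe_exp_ratio(V + 40.0, 10.0); }
static inline double bm(double V) { return 4.0 * std::exp(-(V + 65.0) / 18.0); }
static inline double ah(double V) { return 0.07 * std::exp(-(V + 65.0) / 20.0); }
static inline double bh(double V) { return 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0)); }
static inline double an(double V) { return 0.01 * safe_exp_ratio(V + 55.0, 10.0); }
static inline double bn(double V) { return 0.125 * std::exp(-(V + 65.0) / 80.0); }

static inline double kir_inf(double V, const Params& p) {
  return 1.0 / (1.0 + std::exp((V - p.vhKir) / p.kKir));
}
static inline double r_inf(double V, const Params& p) {
  return 1.0 / (1.0 + std::exp((V - p.vhHCN) / p.kHCN));
}
static inline double a_inf(double V) { return 1.0 / (1.0 + std::exp(-(V + 45.0) / 10.0)); }
static inline double b_inf(double V) { return 1.0 / (1.0 + std::exp((V + 70.0) / 6.0)); }
static inline double z_inf(double V) { return 1.0 / (1.0 + std::exp(-(V + 40.0) / 5.0)); }

static void derivs(const double* s, double* ds, double Iinj, const Params& p) {
  double V = s[0], m = s[1], h = s[2], n = s[3], z = s[4], r = s[5], a = s[6], b = s[7];
  double Vna = V - p.naShift;
  double I = -p.gL * (V - p.EL)
    - p.gNa * m * m * m * h * (V - p.ENa)
    - p.gK * n * n * n * n * (V - p.EK)
    - p.gKir * kir_inf(V, p) * (V - p.EK)
    - p.gHCN * r * (V - p.EH)
    - p.gA * a * a * a * b * (V - p.EK)
    - p.gAdapt * z * (V - p.EK)
    + Iinj;
  ds[0] = I / p.C;
  ds[1] = am(Vna) * (1.0 - m) - bm(Vna) * m;
  ds[2] = ah(Vna) * (1.0 - h) - bh(Vna) * h;
  ds[3] = an(V) * (1.0 - n) - bn(V) * n;
  ds[4] = (z_inf(V) - z) / p.tauAdapt;
  ds[5] = (r_inf(V, p) - r) / p.tauHCN;
  ds[6] = (a_inf(V) - a) / p.tauA;
  ds[7] = (b_inf(V) - b) / p.tauB;
}

static Params unpack(NumericVector pv) {
  Params p;
  p.C = pv["C"]; p.gL = pv["g_leak"]; p.EL = pv["e_leak"];
  p.gNa = pv["g_na"]; p.ENa = pv["e_na"]; p.naShift = pv["na_shift"];
  p.gK = pv["g_kdr"]; p.EK = pv["e_k"];
  p.gKir = pv["g_kir"]; p.vhKir = pv["kir_vhalf"]; p.kKir = pv["kir_slope"];
  p.gHCN = pv["g_hcn"]; p.EH = pv["e_hcn"]; p.tauHCN = pv["hcn_tau"];
  p.vhHCN = pv["hcn_vhalf"]; p.kHCN = pv["hcn_slope"];
  p.gA = pv["g_atype"]; p.tauA = pv["atype_tau_act"]; p.tauB = pv["atype_tau_inact"];
  p.gAdapt = pv["g_adapt"]; p.tauAdapt = pv["adapt_tau"];
  return p;
}

// Steady-state total membrane current (pA) at clamped voltage V, all gates
// at their steady state.  Used from R to locate the resting fixed point.
// [[Rcpp::export(name = ".hh_steady_current")]]
double hh_steady_current(double V, NumericVector pv) {
  Params p = unpack(pv);
  double Vna = V - p.naShift;
  double m = am(Vna) / (am(Vna) + bm(Vna));
  double h = ah(Vna) / (ah(Vna) + bh(Vna));
  double n = an(V) / (an(V) + bn(V));
  double a = a_inf(V), b = b_inf(V), z = z_inf(V), r = r_inf(V, p);
  return p.gL * (V - p.EL)
    + p.gNa * m * m * m * h * (V - p.ENa)
    + p.gK * n * n * n * n * (V - p.EK)
    + p.gKir * kir_inf(V, p) * (V - p.EK)
    + p.gHCN * r * (V - p.EH)
    + p.gA * a * a * a * b * (V - p.EK)
    + p.gAdapt * z * (V - p.EK);
}

// Integrate one sweep.  i_inj is the injected-current waveform (pA) sampled
// at dt_ms; i_noise (same length, possibly all zero) is added to it.
// Returns the voltage trace; attribute "finite" reports integration health.
// [[Rcpp::export(name = ".hh_integrate")]]
NumericVector hh_integrate(NumericVector pv, double dt_ms, double v0,
                           NumericVector i_inj, NumericVector i_noise) {
  Params p = unpack(pv);
  int nstep = i_inj.size();
  NumericVector V(nstep);
  double s[8], ds1[8], ds2[8], ds3[8], ds4[8], tmp[8];
  s[0] = v0;
  double v0na = v0 - p.naShift;
  s[1] = am(v0na) / (am(v0na) + bm(v0na));
  s[2] = ah(v0na) / (ah(v0na) + bh(v0na));
  s[3] = an(v0) / (an(v0) + bn(v0));
  s[4] = z_inf(v0);
  s[5] = r_inf(v0, p);
  s[6] = a_inf(v0);
  s[7] = b_inf(v0);
  bool ok = true;
  for (int i = 0; i < nstep; ++i) {
    V[i] = s[0];
    double I = i_inj[i] + i_noise[i];
    derivs(s, ds1, I, p);
    for (int j = 0; j < 8; ++j) tmp[j] = s[j] + 0.5 * dt_ms * ds1[j];
    derivs(tmp, ds2, I, p);
    for (int j = 0; j < 8; ++j) tmp[j] = s[j] + 0.5 * dt_ms * ds2[j];
    derivs(tmp, ds3, I, p);
    for (int j = 0; j < 8; ++j) tmp[j] = s[j] + dt_ms * ds3[j];
    derivs(tmp, ds4, I, p);
    for (int j = 0; j < 8; ++j)
      s[j] += dt_ms / 6.0 * (ds1[j] + 2.0 * ds2[j] + 2.0 * ds3[j] + ds4[j]);
    if (!std::isfinite(s[0])) { ok = false; break; }
  }
  V.attr("finite") = ok;
  return V;
}
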