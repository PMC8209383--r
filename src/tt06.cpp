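// Ten Tusscher-Panfilov 2006 human ventricular myocyte model and a
// monodomain reaction-diffusion kernel on regular 2D grids.
//
// Two integration paths share the same equations and update ordering:
//  * a scalar path (tt06_step_cpp) evaluating all rate expressions exactly,
//    used for single-cell work and as the dense-time reference;
//  * a table-accelerated tissue kernel (sim_monodomain_cpp) that tabulates
//    the voltage-dependent gate steady states, Rush-Larsen decay factors
//    and current prefactors on a fine Vm lattice with linear interpolation.
//
// State vector layout (19 doubles per node):
//  0 Vm [mV]; 1 m; 2 h; 3 j; 4 xr1; 5 xr2; 6 xs; 7 r; 8 s; 9 d; 10 f;
//  11 f2; 12 fCass; 13 Rbar; 14 Cai; 15 CaSS; 16 CaSR [mM]; 17 Nai; 18 Ki.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

static const int NSTATE = 19;

// physical constants (units as in the published model code)
static const double Rgas = 8314.472;    // mJ/(mol K)
static const double Temp = 310.0;       // K
static const double Frdy = 96485.3415;  // C/mol
static const double RTONF = Rgas * Temp / Frdy;   // mV
static const double FONRT = 1.0 / RTONF;

static const double Cm   = 0.185;       // uF/cm^2 (model normalisation)
static const double Vc   = 0.016404;
static const double Vsr  = 0.001094;
static const double Vss  = 0.00005468;

static const double Ko  = 5.4, Cao = 2.0, Nao = 140.0;
static const double pKNa = 0.03;

static const double Bufc = 0.2,  Kbufc = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Bufss = 0.4, Kbufss = 0.00025;

static const double Vmaxup = 0.006375, Kup = 0.00025;
static const double Vrel = 0.102, Vleak = 0.00036, Vxfer = 0.0038;
static const double k1p = 0.15, k2p = 0.045, k3 = 0.060, k4 = 0.005;
static const double maxsr = 2.5, minsr = 1.0, EC = 1.5;

static const double KmNai = 87.5, KmCa = 1.38, ksat = 0.1, ncgamma = 0.35;
static const double KmK = 1.0, KmNa = 40.0;
static const double KpCa = 0.0005;

static const double inVcF2 = 1.0 / (2.0 * Vc * Frdy);
static const double inVcF  = 1.0 / (Vc * Frdy);
static const double inVssF2 = 1.0 / (2.0 * Vss * Frdy);

// variant codes: 0 epicardial, 1 endocardial, 2 mid-myocardial
struct CellPar {
  double GNa, GK1, Gto, GKr, GKs, GCaL, kNaCa, PNaK, GpCa, GpK, GbNa, GbCa;
  int variant;
};

static CellPar par_from_list(const List& p) {
  CellPar q;
  q.GNa = p["G_Na"]; q.GK1 = p["G_K1"]; q.Gto = p["G_to"];
  q.GKr = p["G_Kr"]; q.GKs = p["G_Ks"]; q.GCaL = p["G_CaL"];
  q.kNaCa = p["k_NaCa"]; q.PNaK = p["P_NaK"];
  q.GpCa = p["G_pCa"]; q.GpK = p["G_pK"];
  q.GbNa = p["G_bNa"]; q.GbCa = p["G_bCa"];
  q.variant = as<int>(p["variant_code"]);
  return q;
}

// ---- gate kinetics -------------------------------------------------------

struct GateRates { double inf, tau; };

static inline GateRates rate_m(double V) {
  double inf = 1.0 / pow(1.0 + exp((-56.86 - V) / 9.03), 2.0);
  double a = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
  double b = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) +
             0.1 / (1.0 + exp((V - 50.0) / 200.0));
  return {inf, a * b};
}
static inline GateRates rate_h(double V) {
  double inf = 1.0 / pow(1.0 + exp((V + 71.55) / 7.43), 2.0);
  double a, b;
  if (V >= -40.0) {
    a = 0.0;
    b = 0.77 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1)));
  } else {
    a = 0.057 * exp(-(V + 80.0) / 6.8);
    b = 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V);
  }
  return {inf, 1.0 / (a + b)};
}
static inline GateRates rate_j(double V) {
  double inf = 1.0 / pow(1.0 + exp((V + 71.55) / 7.43), 2.0);
  double a, b;
  if (V >= -40.0) {
    a = 0.0;
    b = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
  } else {
    a = (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
        (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
    b = 0.02424 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
  }
  return {inf, 1.0 / (a + b)};
}
static inline GateRates rate_xr1(double V) {
  double inf = 1.0 / (1.0 + exp((-26.0 - V) / 7.0));
  double a = 450.0 / (1.0 + exp((-45.0 - V) / 10.0));
  double b = 6.0 / (1.0 + exp((V + 30.0) / 11.5));
  return {inf, a * b};
}
static inline GateRates rate_xr2(double V) {
  double inf = 1.0 / (1.0 + exp((V + 88.0) / 24.0));
  double a = 3.0 / (1.0 + exp((-60.0 - V) / 20.0));
  double b = 1.12 / (1.0 + exp((V - 60.0) / 20.0));
  return {inf, a * b};
}
static inline GateRates rate_xs(double V) {
  double inf = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
  double a = 1400.0 / sqrt(1.0 + exp((5.0 - V) / 6.0));
  double b = 1.0 / (1.0 + exp((V - 35.0) / 15.0));
  return {inf, a * b + 80.0};
}
static inline GateRates rate_r(double V) {
  double inf = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
  double tau = 9.5 * exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  return {inf, tau};
}
static inline GateRates rate_s(double V, int variant) {
  if (variant == 1) {  // endocardial
    double inf = 1.0 / (1.0 + exp((V + 28.0) / 5.0));
    double tau = 1000.0 * exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
    return {inf, tau};
  }
  double inf = 1.0 / (1.0 + exp((V + 20.0) / 5.0));
  double tau = 85.0 * exp(-(V + 45.0) * (V + 45.0) / 320.0) +
               5.0 / (1.0 + exp((V - 20.0) / 5.0)) + 3.0;
  return {inf, tau};
}
static inline GateRates rate_d(double V) {
  double inf = 1.0 / (1.0 + exp((-8.0 - V) / 7.5));
  double a = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
  double b = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
  double c = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
  return {inf, a * b + c};
}
static inline GateRates rate_f(double V) {
  double inf = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
  double tau = 1102.5 * exp(-(V + 27.0) * (V + 27.0) / 225.0) +
               200.0 / (1.0 + exp((13.0 - V) / 10.0)) +
               180.0 / (1.0 + exp((V + 30.0) / 10.0)) + 20.0;
  return {inf, tau};
}
static inline GateRates rate_f2(double V) {
  double inf = 0.67 / (1.0 + exp((V + 35.0) / 7.0)) + 0.33;
  double tau = 562.0 * exp(-(V + 27.0) * (V + 27.0) / 240.0) +
               31.0 / (1.0 + exp((25.0 - V) / 10.0)) +
               80.0 / (1.0 + exp((V + 30.0) / 10.0));
  return {inf, tau};
}
static inline GateRates rate_fcass(double cass) {
  double x = cass / 0.05;
  double inf = 0.6 / (1.0 + x * x) + 0.4;
  double tau = 80.0 / (1.0 + x * x) + 2.0;
  return {inf, tau};
}

static inline double xk1_inf(double VmEK) {
  double a = 0.1 / (1.0 + exp(0.06 * (VmEK - 200.0)));
  double b = (3.0 * exp(0.0002 * (VmEK + 100.0)) + exp(0.1 * (VmEK - 10.0))) /
             (1.0 + exp(-0.5 * VmEK));
  return a / (a + b);
}

// L-type driving-force factor 4 (V-15) F^2/(RT) / (exp(2(V-15)F/RT) - 1),
// finite limit 2F at V = 15 mV
static inline double ical_fac(double V) {
  double dv = V - 15.0;
  double e = 2.0 * dv * FONRT;
  if (fabs(e) < 1e-7) return 2.0 * Frdy;
  return 4.0 * dv * Frdy * Frdy / (Rgas * Temp) / (exp(e) - 1.0);
}

// ---- currents ------------------------------------------------------------

struct Currents {
  double INa, IK1, Ito, IKr, IKs, ICaL, INaCa, INaK, IpCa, IpK, IbCa, IbNa;
  double Irel, Iup, Ileak, Ixfer;
  double Iion;
};

static Currents compute_currents(const double* s, const CellPar& p) {
  double V = s[0];
  double Nai = s[17], Ki = s[18], Cai = s[14], CaSS = s[15], CaSR = s[16];

  double EK  = RTONF * log(Ko / Ki);
  double ENa = RTONF * log(Nao / Nai);
  double EKs = RTONF * log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  double ECa = 0.5 * RTONF * log(Cao / Cai);

  Currents c;
  c.INa = p.GNa * s[1] * s[1] * s[1] * s[2] * s[3] * (V - ENa);
  c.IK1 = p.GK1 * sqrt(Ko / 5.4) * xk1_inf(V - EK) * (V - EK);
  c.Ito = p.Gto * s[7] * s[8] * (V - EK);
  c.IKr = p.GKr * sqrt(Ko / 5.4) * s[4] * s[5] * (V - EK);
  c.IKs = p.GKs * s[6] * s[6] * (V - EKs);

  double ee = exp(2.0 * (V - 15.0) * FONRT);
  c.ICaL = p.GCaL * s[9] * s[10] * s[11] * s[12] * ical_fac(V) *
           (0.25 * CaSS * ee - Cao);

  double e1 = exp(ncgamma * V * FONRT);
  double e2 = exp((ncgamma - 1.0) * V * FONRT);
  c.INaCa = p.kNaCa *
            (e1 * Nai * Nai * Nai * Cao - e2 * Nao * Nao * Nao * Cai * 2.5) /
            ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
             (1.0 + ksat * e2));

  c.INaK = p.PNaK * Ko * Nai /
           ((Ko + KmK) * (Nai + KmNa) *
            (1.0 + 0.1245 * exp(-0.1 * V * FONRT) +
             0.0353 * exp(-V * FONRT)));

  c.IpCa = p.GpCa * Cai / (KpCa + Cai);
  c.IpK  = p.GpK * (V - EK) / (1.0 + exp((25.0 - V) / 5.98));
  c.IbNa = p.GbNa * (V - ENa);
  c.IbCa = p.GbCa * (V - ECa);

  // SR fluxes
  double kCaSR = maxsr - (maxsr - minsr) / (1.0 + (EC / CaSR) * (EC / CaSR));
  double k1 = k1p / kCaSR;
  double O = k1 * CaSS * CaSS * s[13] / (k3 + k1 * CaSS * CaSS);
  c.Irel = Vrel * O * (CaSR - CaSS);
  c.Ileak = Vleak * (CaSR - Cai);
  c.Iup = Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));
  c.Ixfer = Vxfer * (CaSS - Cai);

  c.Iion = c.INa + c.IK1 + c.Ito + c.IKr + c.IKs + c.ICaL + c.INaCa +
           c.INaK + c.IpCa + c.IpK + c.IbCa + c.IbNa;
  return c;
}

// analytic update of a rapidly buffered Ca pool: free concentration after
// adding d_total to the total (free + bound) pool with buffer B, Kd
static inline double buffered_update(double free0, double dtotal,
                                     double B, double Kd) {
  double bound = B * free0 / (free0 + Kd);
  double b = B - bound - dtotal - free0 + Kd;
  double cc = Kd * (bound + dtotal + free0);
  return (sqrt(b * b + 4.0 * cc) - b) / 2.0;
}

// one scalar step: currents at old state -> concentrations -> Rush-Larsen
// gates -> forward-Euler Vm
static void step_scalar(double* s, const CellPar& p, double dt, double istim) {
  Currents c = compute_currents(s, p);
  double V = s[0];

  // Ca subsystem
  double kCaSR = maxsr - (maxsr - minsr) /
                 (1.0 + (EC / s[16]) * (EC / s[16]));
  double k2 = k2p * kCaSR;
  s[13] += dt * (-k2 * s[15] * s[13] + k4 * (1.0 - s[13]));

  double dCaSR = dt * (c.Iup - c.Irel - c.Ileak);
  s[16] = buffered_update(s[16], dCaSR, Bufsr, Kbufsr);

  double dCaSS = dt * (-c.Ixfer * (Vc / Vss) + c.Irel * (Vsr / Vss) -
                       c.ICaL * inVssF2 * Cm);
  s[15] = buffered_update(s[15], dCaSS, Bufss, Kbufss);

  double dCai = dt * (-(c.IbCa + c.IpCa - 2.0 * c.INaCa) * inVcF2 * Cm -
                      (c.Iup - c.Ileak) * (Vsr / Vc) + c.Ixfer);
  s[14] = buffered_update(s[14], dCai, Bufc, Kbufc);

  s[17] += dt * (-(c.INa + c.IbNa + 3.0 * c.INaK + 3.0 * c.INaCa) * inVcF * Cm);
  s[18] += dt * (-(istim + c.IK1 + c.Ito + c.IKr + c.IKs - 2.0 * c.INaK +
                   c.IpK) * inVcF * Cm);

  // gates (Rush-Larsen: contraction toward steady state, stays in [0,1])
  GateRates g;
  g = rate_m(V);   s[1] = g.inf - (g.inf - s[1]) * exp(-dt / g.tau);
  g = rate_h(V);   s[2] = g.inf - (g.inf - s[2]) * exp(-dt / g.tau);
  g = rate_j(V);   s[3] = g.inf - (g.inf - s[3]) * exp(-dt / g.tau);
  g = rate_xr1(V); s[4] = g.inf - (g.inf - s[4]) * exp(-dt / g.tau);
  g = rate_xr2(V); s[5] = g.inf - (g.inf - s[5]) * exp(-dt / g.tau);
  g = rate_xs(V);  s[6] = g.inf - (g.inf - s[6]) * exp(-dt / g.tau);
  g = rate_r(V);   s[7] = g.inf - (g.inf - s[7]) * exp(-dt / g.tau);
  g = rate_s(V, p.variant); s[8] = g.inf - (g.inf - s[8]) * exp(-dt / g.tau);
  g = rate_d(V);   s[9] = g.inf - (g.inf - s[9]) * exp(-dt / g.tau);
  g = rate_f(V);   s[10] = g.inf - (g.inf - s[10]) * exp(-dt / g.tau);
  g = rate_f2(V);  s[11] = g.inf - (g.inf - s[11]) * exp(-dt / g.tau);
  g = rate_fcass(s[15]);
  s[12] = g.inf - (g.inf - s[12]) * exp(-dt / g.tau);

  s[0] = V - dt * (c.Iion + istim);
}

// ---- exported scalar-path API -------------------------------------------

// [[Rcpp::export(name = ".tt06_currents_cpp")]]
NumericVector tt06_currents_cpp(NumericVector state, List params) {
  CellPar p = par_from_list(params);
  Currents c = compute_currents(REAL(state), p);
  return NumericVector::create(
      _["I_Na"] = c.INa, _["I_K1"] = c.IK1, _["I_to"] = c.Ito,
      _["I_Kr"] = c.IKr, _["I_Ks"] = c.IKs, _["I_CaL"] = c.ICaL,
      _["I_NaCa"] = c.INaCa, _["I_NaK"] = c.INaK, _["I_pCa"] = c.IpCa,
      _["I_pK"] = c.IpK, _["I_bCa"] = c.IbCa, _["I_bNa"] = c.IbNa,
      _["I_rel"] = c.Irel, _["I_up"] = c.Iup, _["I_leak"] = c.Ileak,
      _["I_xfer"] = c.Ixfer, _["I_ion"] = c.Iion);
}

// [[Rcpp::export(name = ".tt06_step_cpp")]]
NumericVector tt06_step_cpp(NumericVector state, List params, double dt,
                            double istim, int n_steps = 1) {
  CellPar p = par_from_list(params);
  NumericVector out = clone(state);
  double* s = REAL(out);
  for (int k = 0; k < n_steps; ++k) step_scalar(s, p, dt, istim);
  return out;
}

// paced single-cell run; records (time, vm, cai) at sample_interval_ms
// [[Rcpp::export(name = ".tt06_pace_cpp")]]
List tt06_pace_cpp(NumericVector state0, List params, double cycle_length,
                   int n_beats, double dt, double stim_amp,
                   double stim_dur, double sample_interval_ms) {
  CellPar p = par_from_list(params);
  std::vector<double> s(state0.begin(), state0.end());
  double t_end = cycle_length * n_beats;
  long n_steps = (long)llround(t_end / dt);
  int sample_every = (int)llround(sample_interval_ms / dt);
  if (sample_every < 1) sample_every = 1;

  std::vector<double> tv, vm, cai;
  tv.reserve(n_steps / sample_every + 2);
  vm.reserve(n_steps / sample_every + 2);
  cai.reserve(n_steps / sample_every + 2);

  for (long k = 0; k < n_steps; ++k) {
    double t = k * dt;
    if (k % sample_every == 0) {
      tv.push_back(t); vm.push_back(s[0]); cai.push_back(s[14]);
    }
    double tb = t - cycle_length * std::floor(t / cycle_length);
    double istim = (tb < stim_dur) ? stim_amp : 0.0;
    step_scalar(s.data(), p, dt, istim);
    if (!R_finite(s[0]) || s[0] < -150.0 || s[0] > 100.0)
      stop("cell integration unstable at t = %.3f ms (beat %d)",
           t, (int)(t / cycle_length) + 1);
  }
  tv.push_back(t_end); vm.push_back(s[0]); cai.push_back(s[14]);
  return List::create(_["time_ms"] = wrap(tv), _["vm"] = wrap(vm),
                      _["cai"] = wrap(cai),
                      _["final_state"] = wrap(s));
}

// ---- table-accelerated tissue kernel ------------------------------------

struct VTables {
  double vmin, h, inv_h;
  int n;
  // gate inf and Rush-Larsen decay factor exp(-dt/tau), 11 voltage gates
  std::vector<double> inf[11], rl[11];
  // current prefactors
  std::vector<double> e_ical;   // exp(2(V-15)F/RT)
  std::vector<double> f_ical;   // driving-force factor
  std::vector<double> e1_ncx, e2_ncx;
  std::vector<double> nak_rec;  // voltage factor of I_NaK
  std::vector<double> ipk_rec;
  // inward-rectifier gate on a separate (V - EK) lattice
  double umin, un;
  std::vector<double> xk1;

  void build(double dt, int variant, double vmin_, double vmax_, double h_) {
    vmin = vmin_; h = h_; inv_h = 1.0 / h;
    n = (int)((vmax_ - vmin_) / h_) + 2;
    for (int g = 0; g < 11; ++g) { inf[g].resize(n); rl[g].resize(n); }
    e_ical.resize(n); f_ical.resize(n);
    e1_ncx.resize(n); e2_ncx.resize(n);
    nak_rec.resize(n); ipk_rec.resize(n);
    for (int i = 0; i < n; ++i) {
      double V = vmin + i * h;
      GateRates gr[11] = {rate_m(V), rate_h(V), rate_j(V), rate_xr1(V),
                          rate_xr2(V), rate_xs(V), rate_r(V),
                          rate_s(V, variant), rate_d(V), rate_f(V),
                          rate_f2(V)};
      for (int g = 0; g < 11; ++g) {
        inf[g][i] = gr[g].inf;
        rl[g][i] = exp(-dt / gr[g].tau);
      }
      e_ical[i] = exp(2.0 * (V - 15.0) * FONRT);
      f_ical[i] = ical_fac(V);
      e1_ncx[i] = exp(ncgamma * V * FONRT);
      e2_ncx[i] = exp((ncgamma - 1.0) * V * FONRT);
      nak_rec[i] = 1.0 / (1.0 + 0.1245 * exp(-0.1 * V * FONRT) +
                          0.0353 * exp(-V * FONRT));
      ipk_rec[i] = 1.0 / (1.0 + exp((25.0 - V) / 5.98));
    }
    umin = -160.0;
    int un_i = (int)((360.0) / h_) + 2;
    un = un_i;
    xk1.resize(un_i);
    for (int i = 0; i < un_i; ++i) xk1[i] = xk1_inf(umin + i * h_);
  }

  inline double lookup(const std::vector<double>& tab, double idx_f) const {
    int i = (int)idx_f;
    double w = idx_f - i;
    return tab[i] + (tab[i + 1] - tab[i]) * w;
  }
};

// table-driven single-node step. Reversal potentials are passed in and
// refreshed only every few steps by the caller: intracellular
// concentrations drift on a much slower time scale than dt.
static inline void step_table(double* s, const CellPar& p, const VTables& T,
                              double dt, double istim, double EK, double ENa,
                              double EKs, double ECa) {
  double V = s[0];
  double Nai = s[17], Ki = s[18], Cai = s[14], CaSS = s[15], CaSR = s[16];

  double idx = (V - T.vmin) * T.inv_h;

  double INa = p.GNa * s[1] * s[1] * s[1] * s[2] * s[3] * (V - ENa);
  double uidx = (V - EK - T.umin) * T.inv_h;
  double IK1 = p.GK1 * sqrt(Ko / 5.4) * T.lookup(T.xk1, uidx) * (V - EK);
  double Ito = p.Gto * s[7] * s[8] * (V - EK);
  double IKr = p.GKr * sqrt(Ko / 5.4) * s[4] * s[5] * (V - EK);
  double IKs = p.GKs * s[6] * s[6] * (V - EKs);
  double ICaL = p.GCaL * s[9] * s[10] * s[11] * s[12] * T.lookup(T.f_ical, idx) *
                (0.25 * CaSS * T.lookup(T.e_ical, idx) - Cao);
  double e2 = T.lookup(T.e2_ncx, idx);
  double INaCa = p.kNaCa *
      (T.lookup(T.e1_ncx, idx) * Nai * Nai * Nai * Cao -
       e2 * Nao * Nao * Nao * Cai * 2.5) /
      ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
       (1.0 + ksat * e2));
  double INaK = p.PNaK * Ko * Nai / ((Ko + KmK) * (Nai + KmNa)) *
                T.lookup(T.nak_rec, idx);
  double IpCa = p.GpCa * Cai / (KpCa + Cai);
  double IpK  = p.GpK * (V - EK) * T.lookup(T.ipk_rec, idx);
  double IbNa = p.GbNa * (V - ENa);
  double IbCa = p.GbCa * (V - ECa);

  double kCaSR = maxsr - (maxsr - minsr) / (1.0 + (EC / CaSR) * (EC / CaSR));
  double k1 = k1p / kCaSR;
  double O = k1 * CaSS * CaSS * s[13] / (k3 + k1 * CaSS * CaSS);
  double Irel = Vrel * O * (CaSR - CaSS);
  double Ileak = Vleak * (CaSR - Cai);
  double Iup = Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));
  double Ixfer = Vxfer * (CaSS - Cai);

  double Iion = INa + IK1 + Ito + IKr + IKs + ICaL + INaCa + INaK + IpCa +
                IpK + IbCa + IbNa;

  double k2 = k2p * kCaSR;
  s[13] += dt * (-k2 * CaSS * s[13] + k4 * (1.0 - s[13]));
  s[16] = buffered_update(CaSR, dt * (Iup - Irel - Ileak), Bufsr, Kbufsr);
  s[15] = buffered_update(CaSS,
                          dt * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) -
                                ICaL * inVssF2 * Cm),
                          Bufss, Kbufss);
  s[14] = buffered_update(Cai,
                          dt * (-(IbCa + IpCa - 2.0 * INaCa) * inVcF2 * Cm -
                                (Iup - Ileak) * (Vsr / Vc) + Ixfer),
                          Bufc, Kbufc);
  s[17] += dt * (-(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * inVcF * Cm);
  s[18] += dt * (-(istim + IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK) *
                 inVcF * Cm);

  for (int g = 0; g < 11; ++g) {
    double gi = T.lookup(T.inf[g], idx);
    s[1 + g] = gi - (gi - s[1 + g]) * T.lookup(T.rl[g], idx);
  }
  GateRates fc = rate_fcass(s[15]);
  // dt/tau <= 0.01 here, so a 2nd-order expansion of exp(-x) is exact to ~1e-7
  double x = dt / fc.tau;
  double ex = 1.0 - x + 0.5 * x * x;
  s[12] = fc.inf - (fc.inf - s[12]) * ex;

  s[0] = V - dt * (Iion + istim);
}

// Monodomain operator-split simulation on a 2D sheet.
//
// labels: integer per node, 0 normal / 1 fibrotic (row-major, x fastest).
// Edge diffusivities are harmonic means of node diffusivities; no-flux
// boundaries. In obstacle mode fibrotic nodes are removed from the medium.
// S1 stimuli at stim_nodes; optional S2 cross-field reset of reset_nodes
// when any node of trigger_nodes first crosses -20 mV after the last S1.
//
// [[Rcpp::export(name = ".sim_monodomain_cpp")]]
List sim_monodomain_cpp(int nx, int ny, double dx, IntegerVector labels,
                        double D, double conductivity_factor,
                        List params_normal, List params_fibrotic,
                        NumericVector init_state, double dt,
                        double duration_ms, double post_trigger_ms,
                        NumericVector s1_starts, double s1_duration,
                        double s1_amplitude, IntegerVector stim_nodes,
                        IntegerVector trigger_nodes, IntegerVector reset_nodes,
                        double trigger_threshold,
                        double snapshot_interval_ms, double record_start_ms,
                        bool record_cai, bool obstacle_mode,
                        bool use_tables = true) {
  const int nn = nx * ny;
  if (labels.size() != nn) stop("labels length != nx*ny");
  CellPar pn = par_from_list(params_normal);
  CellPar pf = par_from_list(params_fibrotic);

  // stability bound for the explicit diffusion step
  double Dmax = D;
  double dt_lim = dx * dx / (4.0 * Dmax);
  if (dt > dt_lim)
    stop("dt = %g ms violates the diffusion stability bound %g ms "
         "(D = %g mm^2/ms, dx = %g mm)", dt, dt_lim, D, dx);

  VTables T;
  if (use_tables) T.build(dt, pn.variant, -110.0, 90.0, 0.05);

  // state array
  std::vector<double> S((size_t)nn * NSTATE);
  for (int i = 0; i < nn; ++i)
    std::memcpy(&S[(size_t)i * NSTATE], REAL(init_state),
                NSTATE * sizeof(double));

  // per-node excitability mask and parameter choice
  std::vector<unsigned char> fib(nn), active(nn, 1);
  for (int i = 0; i < nn; ++i) {
    fib[i] = labels[i] != 0;
    if (obstacle_mode && fib[i]) active[i] = 0;
  }

  // edge weights (dt/dx^2 * harmonic mean of node diffusivities)
  std::vector<double> wE(nn, 0.0), wN(nn, 0.0);
  double fac = dt / (dx * dx);
  auto nodeD = [&](int i) -> double {
    if (!active[i]) return 0.0;
    return fib[i] ? D * conductivity_factor : D;
  };
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      int i = y * nx + x;
      if (x + 1 < nx) {
        double a = nodeD(i), b = nodeD(i + 1);
        wE[i] = (a > 0 && b > 0) ? fac * 2.0 * a * b / (a + b) : 0.0;
      }
      if (y + 1 < ny) {
        double a = nodeD(i), b = nodeD(i + nx);
        wN[i] = (a > 0 && b > 0) ? fac * 2.0 * a * b / (a + b) : 0.0;
      }
    }

  // stimulus bookkeeping
  std::vector<int> stim(stim_nodes.begin(), stim_nodes.end());
  std::vector<int> trig(trigger_nodes.begin(), trigger_nodes.end());
  std::vector<int> rset(reset_nodes.begin(), reset_nodes.end());
  int n_s1 = s1_starts.size();
  double last_s1 = n_s1 > 0 ? s1_starts[n_s1 - 1] : -1.0;
  bool s2_armed = (trig.size() > 0);
  bool triggered = false;
  double trigger_time = NA_REAL;

  // recording
  int snap_every = (int)llround(snapshot_interval_ms / dt);
  if (snap_every < 1) snap_every = 1;
  std::vector<float> frames, frames_ca;
  std::vector<double> frame_times;
  std::vector<double> first_act(nn, NA_REAL);
  std::vector<double> vprev(nn);

  // cached reversal potentials, refreshed every rev_every steps
  const int rev_every = 16;
  std::vector<double> EKc(nn), ENac(nn), EKsc(nn), ECac(nn);

  double t_end = duration_ms;
  std::vector<double> vdiff(nn);

  long k = 0;
  double t = 0.0;
  while (t < t_end - 1e-9) {
    // snapshot at the top of the step so t=record_start is included
    if (t >= record_start_ms - 1e-9 && (k % snap_every == 0)) {
      frame_times.push_back(t);
      size_t off = frames.size();
      frames.resize(off + nn);
      for (int i = 0; i < nn; ++i) frames[off + i] = (float)S[(size_t)i * NSTATE];
      if (record_cai) {
        size_t o2 = frames_ca.size();
        frames_ca.resize(o2 + nn);
        for (int i = 0; i < nn; ++i)
          frames_ca[o2 + i] = (float)S[(size_t)i * NSTATE + 14];
      }
    }

    // stimulus current this step
    double istim = 0.0;
    for (int b = 0; b < n_s1; ++b)
      if (t >= s1_starts[b] && t < s1_starts[b] + s1_duration) {
        istim = s1_amplitude; break;
      }

    // refresh cached reversal potentials
    if (k % rev_every == 0) {
      for (int i = 0; i < nn; ++i) {
        const double* s = &S[(size_t)i * NSTATE];
        EKc[i]  = RTONF * log(Ko / s[18]);
        ENac[i] = RTONF * log(Nao / s[17]);
        EKsc[i] = RTONF * log((Ko + pKNa * Nao) / (s[18] + pKNa * s[17]));
        ECac[i] = 0.5 * RTONF * log(Cao / s[14]);
      }
    }

    // reaction (stimulus applied to its nodes afterwards: the forward-Euler
    // Vm and Ki updates are linear in Istim)
    if (use_tables) {
      for (int i = 0; i < nn; ++i) {
        double* s = &S[(size_t)i * NSTATE];
        vprev[i] = s[0];
        if (!active[i]) continue;
        step_table(s, fib[i] ? pf : pn, T, dt, 0.0,
                   EKc[i], ENac[i], EKsc[i], ECac[i]);
      }
    } else {
      for (int i = 0; i < nn; ++i) {
        double* s = &S[(size_t)i * NSTATE];
        vprev[i] = s[0];
        if (!active[i]) continue;
        step_scalar(s, fib[i] ? pf : pn, dt, 0.0);
      }
    }
    if (istim != 0.0) {
      for (size_t q = 0; q < stim.size(); ++q) {
        int i = stim[q];
        if (!active[i]) continue;
        double* s = &S[(size_t)i * NSTATE];
        s[0] += -dt * istim;
        s[18] += dt * (-istim * inVcF * Cm);
      }
    }

    t = (k + 1) * dt;
    ++k;

    // diffusion on the post-reaction field; activation detection on the
    // resulting Vm (-20 mV upcrossing, first only)
    for (int i = 0; i < nn; ++i) vdiff[i] = S[(size_t)i * NSTATE];
    for (int y = 0; y < ny; ++y) {
      int row = y * nx;
      for (int x = 0; x < nx; ++x) {
        int i = row + x;
        if (!active[i]) continue;
        double v = vdiff[i], acc = 0.0;
        if (x + 1 < nx) acc += wE[i] * (vdiff[i + 1] - v);
        if (x > 0)      acc += wE[i - 1] * (vdiff[i - 1] - v);
        if (y + 1 < ny) acc += wN[i] * (vdiff[i + nx] - v);
        if (y > 0)      acc += wN[i - nx] * (vdiff[i - nx] - v);
        double vnew = v + acc;
        S[(size_t)i * NSTATE] = vnew;
        if (vprev[i] < -20.0 && vnew >= -20.0 && ISNA(first_act[i]))
          first_act[i] = t;
      }
    }

    // S2 cross-field reset
    if (s2_armed && !triggered && last_s1 >= 0 &&
        t > last_s1 + s1_duration) {
      bool hit = false;
      for (size_t q = 0; q < trig.size(); ++q) {
        int i = trig[q];
        double v = S[(size_t)i * NSTATE];
        if (vprev[i] < trigger_threshold && v >= trigger_threshold) {
          hit = true; break;
        }
      }
      if (hit) {
        triggered = true;
        trigger_time = t;
        for (size_t q = 0; q < rset.size(); ++q) {
          int i = rset[q];
          std::memcpy(&S[(size_t)i * NSTATE], REAL(init_state),
                      NSTATE * sizeof(double));
        }
        if (post_trigger_ms > 0) t_end = trigger_time + post_trigger_ms;
      }
    }

    // instability guard (checked sparsely to keep the loop tight)
    if ((k & 1023) == 0) {
      for (int i = 0; i < nn; i += 17) {
        double v = S[(size_t)i * NSTATE];
        if (!R_finite(v) || v < -150.0 || v > 100.0)
          stop("tissue integration unstable at t = %.2f ms, node %d", t, i);
      }
    }
    if ((k & 8191) == 0) Rcpp::checkUserInterrupt();
  }

  int n_frames = (int)frame_times.size();
  NumericMatrix vm(nn, n_frames);
  for (int f = 0; f < n_frames; ++f)
    for (int i = 0; i < nn; ++i) vm(i, f) = frames[(size_t)f * nn + i];
  List out = List::create(
      _["vm"] = vm, _["time_ms"] = wrap(frame_times),
      _["first_activation_ms"] = wrap(first_act),
      _["trigger_time_ms"] = trigger_time, _["t_end_ms"] = t_end);
  if (record_cai) {
    NumericMatrix cm(nn, n_frames);
    for (int f = 0; f < n_frames; ++f)
      for (int i = 0; i < nn; ++i) cm(i, f) = frames_ca[(size_t)f * nn + i];
    out["cai"] = cm;
  }
  return out;
}
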