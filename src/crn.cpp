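// Courtemanche-Ramirez-Nattel (CRN) human atrial myocyte model and a
// monodomain reaction-diffusion solver over 2D lattices.
//
// Integration scheme: forward Euler on V and concentrations, Rush-Larsen
// exponential updates on gating variables. Voltage-dependent rate quantities
// are tabulated once per run (0.1 mV grid, linear interpolation) with the
// Rush-Larsen factors exp(-dt/tau) folded into the table, so the inner loop
// is table lookups plus arithmetic.
//
// State layout (21 variables per node):
//   0 V (mV); gates 1 m, 2 h, 3 j, 4 oa, 5 oi, 6 ua, 7 ui, 8 xr, 9 xs,
//   10 d, 11 f, 12 fca, 13 u, 14 v, 15 w; concentrations (mM) 16 Nai,
//   17 Ki, 18 Cai, 19 Caup, 20 Carel.
//
// Conductance scale vector (13 multipliers, 1 = unscaled CRN):
//   0 gNa, 1 gK1, 2 gto, 3 gKr, 4 gCaL, 5 gKur, 6 gKs, 7 INaCa_max,
//   8 INaK_max, 9 Iup_max, 10 Krel, 11 Caup_max, 12 ACh.
// The ACh slot scales an acetylcholine-activated K+ current whose baseline
// conductance is zero in this formulation, so it carries zero current unless
// a nonzero g_ACh is compiled in; it exists because condition tables carry an
// ACh row.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const int NSTATE = 21;
static const int NSCALE = 13;

// physical constants
static const double Rgas = 8.3143;    // J/(mol K)
static const double Temp = 310.0;     // K
static const double Frdy = 96.4867;   // C/mmol
static const double RTF  = Rgas * Temp / Frdy;  // mV
static const double Cm   = 100.0;     // pF

// geometry (um^3)
static const double Vcell = 20100.0;
static const double Vi    = 0.68 * Vcell;       // 13668
static const double Vup   = 0.0552 * Vcell;     // 1109.52
static const double Vrel  = 0.0048 * Vcell;     // 96.48

// external concentrations (mM)
static const double Ko  = 5.4;
static const double Nao = 140.0;
static const double Cao = 1.8;

// maximal conductances / rates (unscaled CRN)
static const double gNa   = 7.8;           // nS/pF
static const double gK1   = 0.09;
static const double gto   = 0.1652;
static const double gKr   = 0.029411765;
static const double gKs   = 0.12941176;
static const double gCaL  = 0.12375;
static const double gbCa  = 0.001131;
static const double gbNa  = 0.0006744375;
static const double gACh  = 0.0;           // placeholder ACh-activated K+
static const double INaKmax  = 0.59933874; // pA/pF
static const double INaCamax = 1600.0;     // pA/pF
static const double IpCamax  = 0.275;      // pA/pF
static const double Iupmax   = 0.005;      // mM/ms
static const double Krel     = 30.0;       // 1/ms
static const double Caupmax  = 15.0;       // mM

static const double KQ10   = 3.0;
static const double gam    = 0.35;
static const double KmNai  = 10.0;
static const double KmKo   = 1.5;
static const double KmNa   = 87.5;
static const double KmCa   = 1.38;
static const double ksat   = 0.1;
static const double Kup    = 0.00092;
static const double tautr  = 180.0;
static const double tauu   = 8.0;
static const double taufca = 2.0;

// buffers
static const double TRPNmax = 0.070, KmTRPN = 0.0005;
static const double CMDNmax = 0.050, KmCMDN = 0.00238;
static const double CSQNmax = 10.0,  KmCSQN = 0.8;

// -------------------------------------------------------------------------
// voltage-dependent rates

struct VRates {
  // inf / tau for the 12 V-dependent gates, order:
  // m h j oa oi ua ui xr xs d f w
  double inf[12];
  double tau[12];
  double ik1r;    // 1/(1+exp(0.07(V+80)))
  double gkurv;   // 0.005 + 0.05/(1+exp(-(V-15)/13))
  double ikrr;    // 1/(1+exp((V+15)/22.4))
  double fnak;    // NaK voltage factor
  double e1;      // exp(gamma VF/RT)
  double e2;      // exp((gamma-1) VF/RT)
};

static void crn_vrates(double V, VRates &r) {
  // m
  double am = (std::fabs(V + 47.13) < 1e-10)
    ? 3.2 : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  double bm = 0.08 * std::exp(-V / 11.0);
  r.inf[0] = am / (am + bm); r.tau[0] = 1.0 / (am + bm);
  // h, j
  double ah, bh, aj, bj;
  if (V < -40.0) {
    ah = 0.135 * std::exp((V + 80.0) / -6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V))
         * (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  } else {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp((V + 10.66) / -11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  }
  r.inf[1] = ah / (ah + bh); r.tau[1] = 1.0 / (ah + bh);
  r.inf[2] = aj / (aj + bj); r.tau[2] = 1.0 / (aj + bj);
  // oa, oi (Ito)
  double aoa = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double boa = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  r.tau[3] = 1.0 / ((aoa + boa) * KQ10);
  r.inf[3] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  double aoi = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  double boi = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  r.tau[4] = 1.0 / ((aoi + boi) * KQ10);
  r.inf[4] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  // ua, ui (IKur)
  double aua = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double bua = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  r.tau[5] = 1.0 / ((aua + bua) * KQ10);
  r.inf[5] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  double aui = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  double bui = std::exp((V - 158.0) / 16.0);
  r.tau[6] = 1.0 / ((aui + bui) * KQ10);
  r.inf[6] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  // xr
  double axr = (std::fabs(V + 14.1) < 1e-10)
    ? 0.0015 : 0.0003 * (V + 14.1) / (1.0 - std::exp(-(V + 14.1) / 5.0));
  double bxr = (std::fabs(V - 3.3328) < 1e-10)
    ? 3.7836118e-4
    : 7.3898e-5 * (V - 3.3328) / (std::exp((V - 3.3328) / 5.1237) - 1.0);
  r.tau[7] = 1.0 / (axr + bxr);
  r.inf[7] = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  // xs
  double axs = (std::fabs(V - 19.9) < 1e-10)
    ? 6.8e-4 : 4e-5 * (V - 19.9) / (1.0 - std::exp(-(V - 19.9) / 17.0));
  double bxs = (std::fabs(V - 19.9) < 1e-10)
    ? 3.15e-4 : 3.5e-5 * (V - 19.9) / (std::exp((V - 19.9) / 9.0) - 1.0);
  r.tau[8] = 0.5 / (axs + bxs);
  r.inf[8] = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
  // d
  if (std::fabs(V + 10.0) < 1e-10) {
    r.tau[9] = 4.579 / (1.0 + std::exp((V + 10.0) / -6.24));
  } else {
    r.tau[9] = (1.0 - std::exp((V + 10.0) / -6.24)) /
      (0.035 * (V + 10.0) * (1.0 + std::exp((V + 10.0) / -6.24)));
  }
  r.inf[9] = 1.0 / (1.0 + std::exp((V + 10.0) / -8.0));
  // f
  r.tau[10] = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  r.inf[10] = std::exp(-(V + 28.0) / 6.9) / (1.0 + std::exp(-(V + 28.0) / 6.9));
  // w
  if (std::fabs(V - 7.9) < 1e-10) {
    r.tau[11] = 6.0 * 0.2 / 1.3;
  } else {
    r.tau[11] = 6.0 * (1.0 - std::exp(-(V - 7.9) / 5.0)) /
      ((1.0 + 0.3 * std::exp(-(V - 7.9) / 5.0)) * (V - 7.9));
  }
  r.inf[11] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
  // current coefficients
  r.ik1r  = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));
  r.gkurv = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
  r.ikrr  = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));
  double sigma = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  double vfrt = V * Frdy / (Rgas * Temp);
  r.fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * vfrt) + 0.0365 * sigma * std::exp(-vfrt));
  r.e1 = std::exp(gam * vfrt);
  r.e2 = std::exp((gam - 1.0) * vfrt);
}

// -------------------------------------------------------------------------
// lookup table: 12 gates x (inf, rl) + 6 coefficients = 30 columns

static const double LUT_VMIN = -120.0;
static const double LUT_VMAX = 80.0;
static const double LUT_STEP = 0.1;
static const int    LUT_NCOL = 30;

struct Lut {
  // float storage: the tabulated quantities are smooth and O(1); float
  // interpolation error (~1e-7 relative) is far below the 0.1 mV grid error.
  // e1/e2 (NaCa exponentials) span a wide range and stay double.
  std::vector<float> tab;
  std::vector<double> e12;
  int nrow;
  double dt;
  void build(double dt_) {
    dt = dt_;
    nrow = (int)std::floor((LUT_VMAX - LUT_VMIN) / LUT_STEP) + 1;
    tab.assign((size_t)nrow * LUT_NCOL, 0.0f);
    e12.assign((size_t)nrow * 2, 0.0);
    VRates r;
    for (int i = 0; i < nrow; ++i) {
      double V = LUT_VMIN + i * LUT_STEP;
      crn_vrates(V, r);
      float *row = &tab[(size_t)i * LUT_NCOL];
      for (int g = 0; g < 12; ++g) {
        row[2 * g]     = (float)r.inf[g];
        row[2 * g + 1] = (float)std::exp(-dt / r.tau[g]);
      }
      row[24] = (float)r.ik1r; row[25] = (float)r.gkurv;
      row[26] = (float)r.ikrr; row[27] = (float)r.fnak;
      e12[2 * i] = r.e1; e12[2 * i + 1] = r.e2;
    }
  }
  inline void lookup(double V, double *out) const {
    double x = (V - LUT_VMIN) / LUT_STEP;
    if (x < 0.0) x = 0.0;
    if (x > nrow - 1.001) x = nrow - 1.001;
    int i0 = (int)x;
    double w = x - i0;
    const float *a = &tab[(size_t)i0 * LUT_NCOL];
    const float *b = a + LUT_NCOL;
    for (int c = 0; c < 28; ++c) out[c] = a[c] + w * (b[c] - a[c]);
    const double *ea = &e12[2 * (size_t)i0];
    out[28] = ea[0] + w * (ea[2] - ea[0]);
    out[29] = ea[1] + w * (ea[3] - ea[1]);
  }
};

// scaled constants for one condition
struct ScaledPars {
  double GNa, GK1, Gto, GKr, GCaL, GKur, GKs, GACh;
  double NaCaMax, NaKMax, IupMax, KrelS, CaupMax;
  double nacaDen;  // (KmNa^3+Nao^3)(KmCa+Cao)
  void set(const double *s) {
    GNa = Cm * gNa * s[0];  GK1 = Cm * gK1 * s[1];  Gto = Cm * gto * s[2];
    GKr = Cm * gKr * s[3];  GCaL = Cm * gCaL * s[4]; GKur = Cm * s[5];
    GKs = Cm * gKs * s[6];  GACh = Cm * gACh * s[12];
    NaCaMax = Cm * INaCamax * s[7];
    NaKMax  = Cm * INaKmax * s[8];
    IupMax  = Iupmax * s[9];
    KrelS   = Krel * s[10];
    CaupMax = Caupmax * s[11];
    nacaDen = (KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao);
  }
};

// fast sigmoid for the SR-release Fn gates (effectively a step function)
static inline double fn_sigmoid(double x) {
  if (x > 40.0) return 1.0;
  if (x < -40.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// one reaction update for one node; st points at 21 state doubles laid out
// strided (stride = number of nodes). Returns dV/dt from ionic currents
// (stimulus included); caller adds the diffusion term.
struct ReactWork {
  double rlu, rlfca, rlv0, rlv1;  // precomputed RL factors
  void set(double dt) {
    rlu   = std::exp(-dt / tauu);
    rlfca = std::exp(-dt / taufca);
    rlv0  = std::exp(-dt / 1.91);          // tau_v at u_inf = 0
    rlv1  = std::exp(-dt / (1.91 + 2.09)); // tau_v at u_inf = 1
  }
};

// Erev: optional cached reversal potentials {ENa, EK, ECa}; when null they
// are recomputed from the concentrations (exact; used by the cell path).
static inline double react_node(double *st, size_t stride, const ScaledPars &P,
                                const Lut &lut, const ReactWork &W,
                                double dt, double Ist,
                                const double *Erev = nullptr) {
  double row[LUT_NCOL];
  double V = st[0];
  lut.lookup(V, row);

  double m = st[stride], h = st[2 * stride], j = st[3 * stride];
  double oa = st[4 * stride], oi = st[5 * stride];
  double ua = st[6 * stride], ui = st[7 * stride];
  double xr = st[8 * stride], xs = st[9 * stride];
  double d = st[10 * stride], f = st[11 * stride], fca = st[12 * stride];
  double u = st[13 * stride], v = st[14 * stride], w = st[15 * stride];
  double Nai = st[16 * stride], Ki = st[17 * stride], Cai = st[18 * stride];
  double Caup = st[19 * stride], Carel = st[20 * stride];

  double ENa, EK, ECa;
  if (Erev) { ENa = Erev[0]; EK = Erev[1]; ECa = Erev[2]; }
  else {
    EK  = RTF * std::log(Ko / Ki);
    ENa = RTF * std::log(Nao / Nai);
    ECa = 0.5 * RTF * std::log(Cao / Cai);
  }

  double INa  = P.GNa * m * m * m * h * j * (V - ENa);
  double IK1  = P.GK1 * row[24] * (V - EK);
  double Ito  = P.Gto * oa * oa * oa * oi * (V - EK);
  double IKur = P.GKur * row[25] * ua * ua * ua * ui * (V - EK);
  double IKr  = P.GKr * xr * row[26] * (V - EK);
  double IKs  = P.GKs * xs * xs * (V - EK);
  double ICaL = P.GCaL * d * f * fca * (V - 65.0);
  double IACh = P.GACh * (V - EK);
  double xna  = KmNai / Nai;
  double INaK = P.NaKMax * row[27] * (1.0 / (1.0 + xna * std::sqrt(xna))) *
                (Ko / (Ko + KmKo));
  double INaCa = P.NaCaMax *
    (row[28] * Nai * Nai * Nai * Cao - row[29] * Nao * Nao * Nao * Cai) /
    (P.nacaDen * (1.0 + ksat * row[29]));
  double IbNa = Cm * gbNa * (V - ENa);
  double IbCa = Cm * gbCa * (V - ECa);
  double IpCa = Cm * IpCamax * Cai / (0.0005 + Cai);

  double Iion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IACh +
                INaK + INaCa + IbNa + IbCa + IpCa;

  // SR fluxes (mM/ms)
  double Irel  = P.KrelS * u * u * v * w * (Carel - Cai);
  double Iup   = P.IupMax / (1.0 + Kup / Cai);
  double Ileak = P.IupMax * Caup / P.CaupMax;
  double Itr   = (Caup - Carel) / tautr;

  double Fn = 1e-12 * Vrel * Irel - (5e-13 / Frdy) * (0.5 * ICaL - 0.2 * INaCa);
  double uinf = fn_sigmoid((Fn - 3.4175e-13) / 13.67e-16);
  double vinf = 1.0 - fn_sigmoid((Fn - 6.835e-14) / 13.67e-16);
  double rlv;
  if (uinf < 1e-8) rlv = W.rlv0;
  else if (uinf > 1.0 - 1e-8) rlv = W.rlv1;
  else rlv = std::exp(-dt / (1.91 + 2.09 * uinf));

  // gate updates (Rush-Larsen)
  st[stride]      = row[0]  + (m  - row[0])  * row[1];
  st[2 * stride]  = row[2]  + (h  - row[2])  * row[3];
  st[3 * stride]  = row[4]  + (j  - row[4])  * row[5];
  st[4 * stride]  = row[6]  + (oa - row[6])  * row[7];
  st[5 * stride]  = row[8]  + (oi - row[8])  * row[9];
  st[6 * stride]  = row[10] + (ua - row[10]) * row[11];
  st[7 * stride]  = row[12] + (ui - row[12]) * row[13];
  st[8 * stride]  = row[14] + (xr - row[14]) * row[15];
  st[9 * stride]  = row[16] + (xs - row[16]) * row[17];
  st[10 * stride] = row[18] + (d  - row[18]) * row[19];
  st[11 * stride] = row[20] + (f  - row[20]) * row[21];
  double fcainf = 1.0 / (1.0 + Cai / 0.00035);
  st[12 * stride] = fcainf + (fca - fcainf) * W.rlfca;
  st[13 * stride] = uinf + (u - uinf) * W.rlu;
  st[14 * stride] = vinf + (v - vinf) * rlv;
  st[15 * stride] = row[22] + (w - row[22]) * row[23];

  // concentrations (forward Euler)
  double FVi = Frdy * Vi;
  st[16 * stride] = Nai + dt * (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) / FVi;
  st[17 * stride] = Ki + dt * (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs - IACh) / FVi;
  double B1 = (2.0 * INaCa - IpCa - ICaL - IbCa) / (2.0 * FVi) +
              (Vup * (Ileak - Iup) + Irel * Vrel) / Vi;
  double kt = KmTRPN + Cai, kc = KmCMDN + Cai;
  double B2 = 1.0 + TRPNmax * KmTRPN / (kt * kt) + CMDNmax * KmCMDN / (kc * kc);
  st[18 * stride] = Cai + dt * B1 / B2;
  st[19 * stride] = Caup + dt * (Iup - Ileak - Itr * Vrel / Vup);
  double kcs = KmCSQN + Carel;
  st[20 * stride] = Carel + dt * (Itr - Irel) /
                    (1.0 + CSQNmax * KmCSQN / (kcs * kcs));

  return -(Iion + Ist) / Cm;
}

// -------------------------------------------------------------------------
// exact RHS (no tables), for verification and equilibrium checks

// [[Rcpp::export]]
NumericVector cpp_crn_derivs(NumericVector state, NumericVector scales,
                             double i_stim = 0.0) {
  if (state.size() != NSTATE) stop("state must have %d elements", NSTATE);
  if (scales.size() != NSCALE) stop("scales must have %d elements", NSCALE);
  for (int i = 0; i < NSTATE; ++i)
    if (!R_finite(state[i]))
      stop("non-finite state variable (index %d): numerical blow-up; reduce dt", i + 1);
  ScaledPars P; P.set(&scales[0]);
  double V = state[0];
  VRates r; crn_vrates(V, r);
  double m = state[1], h = state[2], j = state[3], oa = state[4], oi = state[5];
  double ua = state[6], ui = state[7], xr = state[8], xs = state[9];
  double d = state[10], f = state[11], fca = state[12];
  double u = state[13], v = state[14], w = state[15];
  double Nai = state[16], Ki = state[17], Cai = state[18];
  double Caup = state[19], Carel = state[20];

  double EK = RTF * std::log(Ko / Ki), ENa = RTF * std::log(Nao / Nai);
  double ECa = 0.5 * RTF * std::log(Cao / Cai);
  double INa = P.GNa * m * m * m * h * j * (V - ENa);
  double IK1 = P.GK1 * r.ik1r * (V - EK);
  double Ito = P.Gto * oa * oa * oa * oi * (V - EK);
  double IKur = P.GKur * r.gkurv * ua * ua * ua * ui * (V - EK);
  double IKr = P.GKr * xr * r.ikrr * (V - EK);
  double IKs = P.GKs * xs * xs * (V - EK);
  double ICaL = P.GCaL * d * f * fca * (V - 65.0);
  double IACh = P.GACh * (V - EK);
  double xna = KmNai / Nai;
  double INaK = P.NaKMax * r.fnak * (1.0 / (1.0 + xna * std::sqrt(xna))) *
                (Ko / (Ko + KmKo));
  double INaCa = P.NaCaMax *
    (r.e1 * Nai * Nai * Nai * Cao - r.e2 * Nao * Nao * Nao * Cai) /
    (P.nacaDen * (1.0 + ksat * r.e2));
  double IbNa = Cm * gbNa * (V - ENa);
  double IbCa = Cm * gbCa * (V - ECa);
  double IpCa = Cm * IpCamax * Cai / (0.0005 + Cai);
  double Iion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IACh + INaK +
                INaCa + IbNa + IbCa + IpCa;

  double Irel = P.KrelS * u * u * v * w * (Carel - Cai);
  double Iup = P.IupMax / (1.0 + Kup / Cai);
  double Ileak = P.IupMax * Caup / P.CaupMax;
  double Itr = (Caup - Carel) / tautr;
  double Fn = 1e-12 * Vrel * Irel - (5e-13 / Frdy) * (0.5 * ICaL - 0.2 * INaCa);
  double uinf = fn_sigmoid((Fn - 3.4175e-13) / 13.67e-16);
  double vinf = 1.0 - fn_sigmoid((Fn - 6.835e-14) / 13.67e-16);
  double tauv = 1.91 + 2.09 * uinf;

  NumericVector out(NSTATE);
  out[0] = -(Iion + i_stim) / Cm;
  double infs[12] = {r.inf[0], r.inf[1], r.inf[2], r.inf[3], r.inf[4], r.inf[5],
                     r.inf[6], r.inf[7], r.inf[8], r.inf[9], r.inf[10], r.inf[11]};
  double gates[12] = {m, h, j, oa, oi, ua, ui, xr, xs, d, f, w};
  int outidx[12] = {1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 15};
  for (int g = 0; g < 12; ++g)
    out[outidx[g]] = (infs[g] - gates[g]) / r.tau[g];
  double fcainf = 1.0 / (1.0 + Cai / 0.00035);
  out[12] = (fcainf - fca) / taufca;
  out[13] = (uinf - u) / tauu;
  out[14] = (vinf - v) / tauv;
  double FVi = Frdy * Vi;
  out[16] = (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) / FVi;
  out[17] = (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs - IACh) / FVi;
  double B1 = (2.0 * INaCa - IpCa - ICaL - IbCa) / (2.0 * FVi) +
              (Vup * (Ileak - Iup) + Irel * Vrel) / Vi;
  double kt = KmTRPN + Cai, kc = KmCMDN + Cai;
  double B2 = 1.0 + TRPNmax * KmTRPN / (kt * kt) + CMDNmax * KmCMDN / (kc * kc);
  out[18] = B1 / B2;
  out[19] = Iup - Ileak - Itr * Vrel / Vup;
  double kcs = KmCSQN + Carel;
  out[20] = (Itr - Irel) / (1.0 + CSQNmax * KmCSQN / (kcs * kcs));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_crn_initial_state() {
  NumericVector s(NSTATE);
  s[0] = -81.18;  s[1] = 2.908e-3; s[2] = 9.649e-1; s[3] = 9.775e-1;
  s[4] = 3.043e-2; s[5] = 9.992e-1; s[6] = 4.966e-3; s[7] = 9.986e-1;
  s[8] = 3.296e-5; s[9] = 1.869e-2; s[10] = 1.367e-4; s[11] = 9.996e-1;
  s[12] = 7.755e-1; s[13] = 2.35e-112; s[14] = 1.0; s[15] = 9.992e-1;
  s[16] = 11.17; s[17] = 139.0; s[18] = 1.013e-4; s[19] = 1.488; s[20] = 1.488;
  s.attr("names") = CharacterVector::create(
    "V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs", "d", "f", "fCa",
    "u", "v", "w", "Na_i", "K_i", "Ca_i", "Ca_up", "Ca_rel");
  return s;
}

// -------------------------------------------------------------------------
// single-cell run

// [[Rcpp::export]]
List cpp_cell_run(NumericVector state0, NumericVector scales, double dt,
                  double duration, NumericVector stim_times, double stim_dur,
                  double stim_amp, double record_dt) {
  if (state0.size() != NSTATE) stop("bad state length");
  if (scales.size() != NSCALE) stop("bad scales length");
  if (dt <= 0 || duration <= 0) stop("dt and duration must be positive");
  ScaledPars P; P.set(&scales[0]);
  Lut lut; lut.build(dt);
  ReactWork W; W.set(dt);

  std::vector<double> st(state0.begin(), state0.end());
  long nsteps = (long)std::llround(duration / dt);
  int rec_every = std::max(1, (int)std::llround(record_dt / dt));
  long nrec = nsteps / rec_every + 1;
  NumericVector tout(nrec), vout(nrec), caout(nrec);

  // stimulus bookkeeping: sorted start times assumed
  int nstim = stim_times.size();
  int sidx = 0;

  // activation detection (per-beat max dV/dt and its time)
  std::vector<double> act_t, act_dvdt;
  int phase = 0; double curmax = -1e30, curt = 0.0;

  long ri = 0;
  tout[0] = 0.0; vout[0] = st[0]; caout[0] = st[18];
  ri = 1;
  for (long k = 0; k < nsteps; ++k) {
    double t = k * dt;
    double Ist = 0.0;
    while (sidx < nstim && t >= stim_times[sidx] + stim_dur) ++sidx;
    if (sidx < nstim && t >= stim_times[sidx] && t < stim_times[sidx] + stim_dur)
      Ist = -stim_amp;  // depolarizing
    double Vold = st[0];
    double dv = react_node(st.data(), 1, P, lut, W, dt, Ist);
    double Vnew = Vold + dt * dv;
    st[0] = Vnew;
    if (!(Vnew > -150.0 && Vnew < 200.0))
      stop("numerical blow-up at t=%.3f ms (V=%.1f); reduce dt", t, Vnew);
    // activation machine
    double slope = (Vnew - Vold) / dt;
    if (phase == 0) {
      if (Vnew >= -40.0) { phase = 1; curmax = slope; curt = t; }
    } else if (phase == 1) {
      if (slope > curmax) { curmax = slope; curt = t; }
      if (slope < 0.0) { act_t.push_back(curt); act_dvdt.push_back(curmax); phase = 2; }
    } else {
      if (Vnew < -50.0) phase = 0;
    }
    if ((k + 1) % rec_every == 0 && ri < nrec) {
      tout[ri] = (k + 1) * dt; vout[ri] = st[0]; caout[ri] = st[18];
      ++ri;
    }
  }
  return List::create(
    _["time"] = tout, _["V"] = vout, _["Ca_i"] = caout,
    _["final_state"] = NumericVector(st.begin(), st.end()),
    _["act_times"] = NumericVector(act_t.begin(), act_t.end()),
    _["act_dvdt"] = NumericVector(act_dvdt.begin(), act_dvdt.end()));
}

// [[Rcpp::export]]
NumericVector cpp_cell_steady(NumericVector scales, double dt, double duration) {
  NumericVector s0 = cpp_crn_initial_state();
  List out = cpp_cell_run(s0, scales, dt, duration, NumericVector(0), 2.0, 0.0,
                          duration);
  NumericVector fs = out["final_state"];
  fs.attr("names") = s0.attr("names");
  return fs;
}

// -------------------------------------------------------------------------
// 2D monodomain tissue run
//
// Geometry: nx x ny lattice, spacing dx (mm), column-major node index
// idx = ix + nx*iy (ix fastest), matching R matrix layout with nx rows.
// mask[idx] TRUE marks fibrotic (non-conducting, non-reacting) nodes.
// Diffusion tensor per node from fiber angle theta, longitudinal D (mm^2/ms)
// and anisotropy ratio (D_T = D_L / ratio). No-flux boundaries and no-flux
// at masked nodes.

// [[Rcpp::export]]
List cpp_tissue_run(int nx, int ny, double dx, LogicalVector mask,
                    NumericVector theta, NumericVector DL, double aniso_ratio,
                    NumericVector scales, NumericVector state0, double dt,
                    double duration, IntegerVector stim_nodes,
                    NumericVector stim_times, double stim_dur, double stim_amp,
                    double record_dt, double record_start,
                    IntegerVector probe_nodes, double probe_dt,
                    IntegerVector stim2_nodes = IntegerVector(0),
                    NumericVector stim2_times = NumericVector(0),
                    bool periodic = false) {
  int N = nx * ny;
  if (mask.size() != N || theta.size() != N || DL.size() != N)
    stop("mask/theta/DL must have nx*ny elements");
  if (state0.size() != NSTATE && state0.size() != (R_xlen_t)NSTATE * N)
    stop("state0 must have 21 or 21*N elements");
  if (aniso_ratio < 1.0) stop("anisotropy ratio must be >= 1");
  ScaledPars P; P.set(&scales[0]);
  Lut lut; lut.build(dt);
  ReactWork W; W.set(dt);

  // state: node-major (array-of-structs), st[node*NSTATE + var] — each node
  // touches all 21 variables every step, so contiguity per node wins.
  // The R-facing state0/final_state use the transposed (var-major) layout.
  std::vector<double> st((size_t)NSTATE * N);
  if (state0.size() == NSTATE) {
    for (int i = 0; i < N; ++i)
      for (int v = 0; v < NSTATE; ++v) st[(size_t)i * NSTATE + v] = state0[v];
  } else {
    for (int v = 0; v < NSTATE; ++v)
      for (int i = 0; i < N; ++i)
        st[(size_t)i * NSTATE + v] = state0[(R_xlen_t)v * N + i];
  }

  // diffusion tensors
  std::vector<double> Dxx(N), Dyy(N), Dxy(N);
  for (int i = 0; i < N; ++i) {
    double dl = DL[i], dtr = dl / aniso_ratio;
    double c = std::cos(theta[i]), s = std::sin(theta[i]);
    Dxx[i] = dl * c * c + dtr * s * s;
    Dyy[i] = dl * s * s + dtr * c * c;
    Dxy[i] = (dl - dtr) * c * s;
  }
  std::vector<char> msk(N);
  for (int i = 0; i < N; ++i) msk[i] = mask[i] ? 1 : 0;

  std::vector<char> stim_mask(N, 0), stim2_mask(N, 0);
  for (int k = 0; k < stim_nodes.size(); ++k) {
    int n = stim_nodes[k];
    if (n < 0 || n >= N) stop("stimulus node out of range");
    stim_mask[n] = 1;
  }
  for (int k = 0; k < stim2_nodes.size(); ++k) {
    int n = stim2_nodes[k];
    if (n < 0 || n >= N) stop("stimulus node out of range");
    stim2_mask[n] = 1;
  }
  int nstim2 = stim2_times.size();

  long nsteps = (long)std::llround(duration / dt);
  int rec_every = std::max(1, (int)std::llround(record_dt / dt));
  long rec_start_step = (long)std::llround(record_start / dt);
  long nframes = 0;
  for (long k = rec_start_step; k <= nsteps; k += rec_every) ++nframes;
  NumericMatrix frames((int)nframes, N);
  NumericVector frame_times(nframes);

  int nprobe = probe_nodes.size();
  int probe_every = std::max(1, (int)std::llround(probe_dt / dt));
  long nprec = nsteps / probe_every + 1;
  NumericMatrix probes((int)nprec, std::max(nprobe, 1));
  NumericVector probe_times(nprec);

  // activation machinery
  std::vector<int> phase(N, 0);
  std::vector<double> curmax(N, -1e30), curt(N, 0.0);
  std::vector<int> act_node; std::vector<double> act_time, act_slope;
  act_node.reserve(100000); act_time.reserve(100000);

  std::vector<double> lap(N), Vold(N);
  // cached reversal potentials, refreshed every 1 ms (concentrations drift
  // on second scales; the fast Cai transient only feeds the small IbCa term)
  std::vector<double> Erev((size_t)3 * N);
  int erev_every = std::max(1, (int)std::llround(1.0 / dt));
  auto refresh_erev = [&]() {
    for (int i = 0; i < N; ++i) {
      const double *s = &st[(size_t)i * NSTATE];
      Erev[3 * (size_t)i]     = RTF * std::log(Nao / s[16]);
      Erev[3 * (size_t)i + 1] = RTF * std::log(Ko / s[17]);
      Erev[3 * (size_t)i + 2] = 0.5 * RTF * std::log(Cao / s[18]);
    }
  };
  refresh_erev();
  double dx2 = dx * dx;
  int nstim = stim_times.size();
  auto Vat = [&](int i) -> double & { return st[(size_t)i * NSTATE]; };

  long fi = 0, pi = 0;
  auto record_frame = [&](long k) {
    if (fi < nframes) {
      frame_times[fi] = k * dt;
      for (int i = 0; i < N; ++i) frames((int)fi, i) = Vat(i);
      ++fi;
    }
  };
  auto record_probe = [&](long k) {
    if (pi < nprec) {
      probe_times[pi] = k * dt;
      for (int p = 0; p < nprobe; ++p) probes((int)pi, p) = Vat(probe_nodes[p]);
      ++pi;
    }
  };
  if (rec_start_step == 0) record_frame(0);
  if (nprobe > 0) record_probe(0);

  bool aborted = false; double abort_time = NA_REAL;

  for (long k = 0; k < nsteps && !aborted; ++k) {
    double t = k * dt;
    if (k > 0 && k % erev_every == 0) refresh_erev();
    // stimulus active?
    double Ist_now = 0.0;
    for (int si = 0; si < nstim; ++si) {
      if (t >= stim_times[si] && t < stim_times[si] + stim_dur) {
        Ist_now = -stim_amp; break;
      }
      if (stim_times[si] > t) break;
    }
    double Ist2_now = 0.0;
    for (int si = 0; si < nstim2; ++si) {
      if (t >= stim2_times[si] && t < stim2_times[si] + stim_dur) {
        Ist2_now = -stim_amp; break;
      }
      if (stim2_times[si] > t) break;
    }
    // diffusion from old V
    for (int i = 0; i < N; ++i) Vold[i] = Vat(i);
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) {
        int i = ix + nx * iy;
        if (msk[i]) { lap[i] = 0.0; continue; }
        double vi = Vold[i], L = 0.0;
        // neighbour indices; -1 marks a no-flux boundary (open sheet)
        int e = (ix + 1 < nx) ? i + 1 : (periodic ? i + 1 - nx : -1);
        int wst = (ix - 1 >= 0) ? i - 1 : (periodic ? i - 1 + nx : -1);
        int n = (iy + 1 < ny) ? i + nx : (periodic ? i + nx - nx * ny : -1);
        int s = (iy - 1 >= 0) ? i - nx : (periodic ? i - nx + nx * ny : -1);
        // x faces
        if (e >= 0 && !msk[e])
          L += 0.5 * (Dxx[i] + Dxx[e]) * (Vold[e] - vi) / dx2;
        if (wst >= 0 && !msk[wst])
          L += 0.5 * (Dxx[i] + Dxx[wst]) * (Vold[wst] - vi) / dx2;
        // y faces
        if (n >= 0 && !msk[n])
          L += 0.5 * (Dyy[i] + Dyy[n]) * (Vold[n] - vi) / dx2;
        if (s >= 0 && !msk[s])
          L += 0.5 * (Dyy[i] + Dyy[s]) * (Vold[s] - vi) / dx2;
        // cross terms (all 8 neighbours present and unmasked)
        if (e >= 0 && wst >= 0 && n >= 0 && s >= 0) {
          int ne = (ix + 1 >= nx) ? n + 1 - nx : n + 1;
          int nw = (ix - 1 < 0) ? n - 1 + nx : n - 1;
          int se = (ix + 1 >= nx) ? s + 1 - nx : s + 1;
          int sw = (ix - 1 < 0) ? s - 1 + nx : s - 1;
          if (!msk[e] && !msk[wst] && !msk[n] && !msk[s] &&
              !msk[ne] && !msk[nw] && !msk[se] && !msk[sw]) {
            L += (Dxy[e] * (Vold[ne] - Vold[se]) - Dxy[wst] * (Vold[nw] - Vold[sw]))
                 / (4.0 * dx2);
            L += (Dxy[n] * (Vold[ne] - Vold[nw]) - Dxy[s] * (Vold[se] - Vold[sw]))
                 / (4.0 * dx2);
          }
        }
        lap[i] = L;
      }
    }
    // reaction + integrate
    for (int i = 0; i < N; ++i) {
      if (msk[i]) continue;
      double Ist = (Ist_now != 0.0 && stim_mask[i]) ? Ist_now : 0.0;
      if (Ist2_now != 0.0 && stim2_mask[i]) Ist += Ist2_now;
      double vold = Vat(i);
      double dvion = react_node(&st[(size_t)i * NSTATE], 1, P, lut, W, dt, Ist,
                                &Erev[3 * (size_t)i]);
      double vnew = vold + dt * (dvion + lap[i]);
      Vat(i) = vnew;
      if (!(vnew > -150.0 && vnew < 200.0)) {
        aborted = true; abort_time = t;
      }
      // activation machine
      double slope = (vnew - vold) / dt;
      if (phase[i] == 0) {
        if (vnew >= -40.0) { phase[i] = 1; curmax[i] = slope; curt[i] = t; }
      } else if (phase[i] == 1) {
        if (slope > curmax[i]) { curmax[i] = slope; curt[i] = t; }
        if (slope < 0.0) {
          act_node.push_back(i); act_time.push_back(curt[i]);
          act_slope.push_back(curmax[i]);
          phase[i] = 2;
        }
      } else {
        if (vnew < -50.0) phase[i] = 0;
      }
    }
    long k1 = k + 1;
    if (k1 >= rec_start_step && (k1 - rec_start_step) % rec_every == 0)
      record_frame(k1);
    if (nprobe > 0 && k1 % probe_every == 0) record_probe(k1);
    if (k % 40000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector finalV(N);
  for (int i = 0; i < N; ++i) finalV[i] = Vat(i);
  NumericVector final_state((R_xlen_t)NSTATE * N);
  for (int v = 0; v < NSTATE; ++v)
    for (int i = 0; i < N; ++i)
      final_state[(R_xlen_t)v * N + i] = st[(size_t)i * NSTATE + v];

  return List::create(
    _["frames"] = frames, _["frame_times"] = frame_times,
    _["act_node"] = IntegerVector(act_node.begin(), act_node.end()),
    _["act_time"] = NumericVector(act_time.begin(), act_time.end()),
    _["act_dvdt"] = NumericVector(act_slope.begin(), act_slope.end()),
    _["probes"] = probes, _["probe_times"] = probe_times,
    _["final_V"] = finalV, _["final_state"] = final_state,
    _["aborted"] = aborted, _["abort_time"] = abort_time);
}
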