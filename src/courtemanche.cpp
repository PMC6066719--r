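// Courtemanche-Ramirez-Nattel (1998) human atrial membrane kinetics with
// CAF conductance remodeling and the Kneller acetylcholine-activated K+
// current, plus the monodomain time-steppers (forward Euler reaction,
// exact spectral diffusion propagator applied to V via dense per-axis
// matrices, Lie or Strang splitting).
//
// State layout (21 rows):
//  0 V, 1 m, 2 h, 3 j, 4 oa, 5 oi, 6 ua, 7 ui, 8 xr, 9 xs,
// 10 d, 11 f, 12 fca, 13 u, 14 v, 15 w, 16 Nai, 17 Ki, 18 Cai,
// 19 Caup, 20 Carel
//
// Parameter vector layout (see R/ionic-model.R, must stay in sync):
//  0 gNa, 1 gK1, 2 gto, 3 gKr, 4 gKs, 5 gCaL, 6 gKur_scale, 7 gbNa,
//  8 gbCa, 9 INaK_max, 10 INaCa_max, 11 IpCa_max, 12 Iup_max, 13 krel,
// 14 ACh_nM, 15 Cm

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double R_GAS = 8.3143;     // J/(mol K)
static const double TEMP  = 310.0;      // K
static const double FARAD = 96.4867;    // C/mmol
static const double RTF   = R_GAS * TEMP / FARAD; // mV
static const double Na_o  = 140.0;      // mM
static const double K_o   = 5.4;
static const double Ca_o  = 1.8;
static const double V_i   = 13668.0;    // um^3
static const double V_up  = 1109.52;
static const double V_rel = 96.48;
static const double KmNai = 10.0;
static const double KmKo  = 1.5;
static const double KmNa3 = 87.5 * 87.5 * 87.5;
static const double KmCa  = 1.38;
static const double Ksat  = 0.1;
static const double GAMMA = 0.35;
static const double K_up  = 0.00092;
static const double Caup_max = 15.0;
static const double CMDN  = 0.05,  KmCMDN = 0.00238;
static const double TRPN  = 0.07,  KmTRPN = 0.0005;
static const double CSQN  = 10.0,  KmCSQN = 0.8;
static const double TAU_TR = 180.0;
static const double KQ10  = 3.0;

// number of tabulated voltage-dependent quantities
static const int NTAB = 31;

// Voltage-dependent rate/factor evaluation (exact formulas, singular
// points handled by their limits). Order must match the stepping code.
static void vrates(double V, double* r) {
  double a, b, tau;
  // I_Na gates (alpha/beta form)
  r[0] = std::fabs(V + 47.13) < 1e-10 ? 3.2
       : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  r[1] = 0.08 * std::exp(-V / 11.0);
  if (V < -40.0) {
    r[2] = 0.135 * std::exp(-(V + 80.0) / 6.8);
    r[3] = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    r[4] = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V))
           * (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    r[5] = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  } else {
    r[2] = 0.0;
    r[3] = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    r[4] = 0.0;
    r[5] = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  }
  // I_to gates
  a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  r[6] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  r[7] = KQ10 * (a + b);
  a = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  b = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  r[8] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  r[9] = KQ10 * (a + b);
  // I_Kur gates (ua activation shares the oa rate functions)
  a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  r[10] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  r[11] = KQ10 * (a + b);
  a = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  b = std::exp((V - 158.0) / 16.0);
  r[12] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  r[13] = KQ10 * (a + b);
  // I_Kr activation
  a = std::fabs(V + 14.1) < 1e-10 ? 0.0015
    : 0.0003 * (V + 14.1) / (1.0 - std::exp(-(V + 14.1) / 5.0));
  b = std::fabs(V - 3.3328) < 1e-10 ? 3.7836118e-4
    : 7.3898e-5 * (V - 3.3328) / (std::exp((V - 3.3328) / 5.1237) - 1.0);
  r[14] = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  r[15] = a + b;
  // I_Ks activation
  a = std::fabs(V - 19.9) < 1e-10 ? 0.00068
    : 4e-5 * (V - 19.9) / (1.0 - std::exp(-(V - 19.9) / 17.0));
  b = std::fabs(V - 19.9) < 1e-10 ? 0.000315
    : 3.5e-5 * (V - 19.9) / (std::exp((V - 19.9) / 9.0) - 1.0);
  r[16] = std::pow(1.0 + std::exp(-(V - 19.9) / 12.7), -0.5);
  r[17] = 2.0 * (a + b);  // tau_xs = 0.5/(a+b)
  // I_CaL gates
  r[18] = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  if (std::fabs(V + 10.0) < 1e-10) {
    tau = 4.579 / (1.0 + std::exp(-(V + 10.0) / 6.24));
  } else {
    double e = std::exp(-(V + 10.0) / 6.24);
    tau = (1.0 - e) / (0.035 * (V + 10.0) * (1.0 + e));
  }
  r[19] = 1.0 / tau;
  r[20] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  r[21] = (0.0197 * std::exp(-std::pow(0.0337 * (V + 10.0), 2)) + 0.02) / 9.0;
  // Ca-release w gate
  r[22] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
  if (std::fabs(V - 7.9) < 1e-10) {
    tau = 6.0 * 0.2 / 1.3;
  } else {
    double e = std::exp(-(V - 7.9) / 5.0);
    tau = 6.0 * (1.0 - e) / ((1.0 + 0.3 * e) * (V - 7.9));
  }
  r[23] = 1.0 / tau;
  // current voltage factors
  r[24] = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));                 // I_K1
  r[25] = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));      // g_Kur(V)
  r[26] = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));                // I_Kr
  double sigma = (std::exp(Na_o / 67.3) - 1.0) / 7.0;
  double fvrt = V / RTF;
  r[27] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * fvrt) + 0.0365 * sigma * std::exp(-fvrt));
  r[28] = std::exp(GAMMA * fvrt);
  r[29] = std::exp((GAMMA - 1.0) * fvrt);
  r[30] = 0.0517 + 0.4516 / (1.0 + std::exp((V + 59.53) / 17.18));  // I_KACh
}

// Kneller et al. dose-response factor; ACh in nM, internal dose law in uM.
static double kach_dose(double ach_nM) {
  if (ach_nM <= 0.0) return 0.0;
  double uM = ach_nM * 1e-3;
  return 10.0 / (1.0 + 9.13652 / std::pow(uM, 0.477811));
}

struct Pars {
  double gNa, gK1, gto, gKr, gKs, gCaL, gKurS, gbNa, gbCa,
         INaK, INaCa, IpCa, Iup, krel, ach, Cm, gAChD;
  explicit Pars(const arma::vec& p) {
    gNa = p[0]; gK1 = p[1]; gto = p[2]; gKr = p[3]; gKs = p[4];
    gCaL = p[5]; gKurS = p[6]; gbNa = p[7]; gbCa = p[8]; INaK = p[9];
    INaCa = p[10]; IpCa = p[11]; Iup = p[12]; krel = p[13]; ach = p[14];
    Cm = p[15];
    gAChD = kach_dose(ach);
  }
};

// One forward-Euler reaction update of a single cell given its rate
// row r[NTAB]; writes the updated state in place; returns V before update.
static inline double cell_euler(double* s, const double* r, const Pars& P,
                                double istim, double dt, double* itot_out) {
  const double V = s[0];
  const double ENa = RTF * std::log(Na_o / s[16]);
  const double EK  = RTF * std::log(K_o / s[17]);
  const double ECa = 0.5 * RTF * std::log(Ca_o / s[18]);

  const double m = s[1], h = s[2], j = s[3];
  const double INa  = P.gNa * m * m * m * h * j * (V - ENa);
  const double IK1  = P.gK1 * r[24] * (V - EK);
  const double Ito  = P.gto * s[4] * s[4] * s[4] * s[5] * (V - EK);
  const double IKur = P.gKurS * r[25] * s[6] * s[6] * s[6] * s[7] * (V - EK);
  const double IKr  = P.gKr * r[26] * s[8] * (V - EK);
  const double IKs  = P.gKs * s[9] * s[9] * (V - EK);
  const double ICaL = P.gCaL * s[10] * s[11] * s[12] * (V - 65.0);
  const double INaK = P.INaK * r[27] / (1.0 + std::pow(KmNai / s[16], 1.5))
                      * (K_o / (K_o + KmKo));
  const double Nai3 = s[16] * s[16] * s[16];
  const double INaCa = P.INaCa * (r[28] * Nai3 * Ca_o - r[29] * Na_o * Na_o * Na_o * s[18])
                      / ((KmNa3 + Na_o * Na_o * Na_o) * (KmCa + Ca_o)
                         * (1.0 + Ksat * r[29]));
  const double IbNa = P.gbNa * (V - ENa);
  const double IbCa = P.gbCa * (V - ECa);
  const double IpCa = P.IpCa * s[18] / (0.0005 + s[18]);
  const double IKACh = P.gAChD * r[30] * (V - EK);

  const double Itot = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa
                    + INaK + INaCa + IbNa + IbCa + IKACh;
  if (itot_out) *itot_out = Itot;

  // SR calcium subsystem
  const double Irel = P.krel * s[13] * s[13] * s[14] * s[15] * (s[20] - s[18]);
  const double Itr  = (s[19] - s[20]) / TAU_TR;
  const double Iup  = P.Iup / (1.0 + K_up / s[18]);
  const double Iupleak = P.Iup * s[19] / Caup_max;
  const double Fn = 1e3 * (1e-15 * V_rel * Irel
                   - 1e-15 / (2.0 * FARAD) * (0.5 * ICaL - 0.2 * INaCa) * P.Cm);
  const double u_inf = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  const double v_inf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  const double tau_v = 1.91 + 2.09 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  const double fca_inf = 1.0 / (1.0 + s[18] / 0.00035);

  // derivatives
  const double dV = -(Itot + istim);
  const double dNai = (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) * P.Cm / (FARAD * V_i);
  const double dKi  = (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs - IKACh)
                      * P.Cm / (FARAD * V_i);
  const double B1 = (2.0 * INaCa - IpCa - ICaL - IbCa) * P.Cm / (2.0 * FARAD * V_i)
                  + (V_up * (Iupleak - Iup) + Irel * V_rel) / V_i;
  const double B2 = 1.0 + TRPN * KmTRPN / std::pow(s[18] + KmTRPN, 2)
                  + CMDN * KmCMDN / std::pow(s[18] + KmCMDN, 2);
  const double dCaup  = Iup - Iupleak - Itr * V_rel / V_up;
  const double dCarel = (Itr - Irel)
                      / (1.0 + CSQN * KmCSQN / std::pow(s[20] + KmCSQN, 2));

  s[0]  += dt * dV;
  s[1]  += dt * (r[0] * (1.0 - m) - r[1] * m);
  s[2]  += dt * (r[2] * (1.0 - h) - r[3] * h);
  s[3]  += dt * (r[4] * (1.0 - j) - r[5] * j);
  s[4]  += dt * (r[6]  - s[4]) * r[7];
  s[5]  += dt * (r[8]  - s[5]) * r[9];
  s[6]  += dt * (r[10] - s[6]) * r[11];
  s[7]  += dt * (r[12] - s[7]) * r[13];
  s[8]  += dt * (r[14] - s[8]) * r[15];
  s[9]  += dt * (r[16] - s[9]) * r[17];
  s[10] += dt * (r[18] - s[10]) * r[19];
  s[11] += dt * (r[20] - s[11]) * r[21];
  s[12] += dt * (fca_inf - s[12]) / 2.0;
  s[13] += dt * (u_inf - s[13]) / 8.0;
  s[14] += dt * (v_inf - s[14]) / tau_v;
  s[15] += dt * (r[22] - s[15]) * r[23];
  s[16] += dt * dNai;
  s[17] += dt * dKi;
  s[18] += dt * B1 / B2;
  s[19] += dt * dCaup;
  s[20] += dt * dCarel;
  return V;
}

// Exact (non-tabulated) evaluation of all membrane currents at a state.
// [[Rcpp::export]]
NumericVector cpp_ionic_currents(NumericVector state, NumericVector params) {
  if (state.size() != 21) stop("state must have 21 elements");
  for (int i = 0; i < 21; ++i)
    if (!R_finite(state[i])) stop("non-finite value in membrane state");
  arma::vec p(params.begin(), params.size());
  Pars P(p);
  double r[NTAB];
  const double* s = state.begin();
  vrates(s[0], r);
  const double V = s[0];
  const double ENa = RTF * std::log(Na_o / s[16]);
  const double EK  = RTF * std::log(K_o / s[17]);
  const double ECa = 0.5 * RTF * std::log(Ca_o / s[18]);
  double INa  = P.gNa * s[1] * s[1] * s[1] * s[2] * s[3] * (V - ENa);
  double IK1  = P.gK1 * r[24] * (V - EK);
  double Ito  = P.gto * s[4] * s[4] * s[4] * s[5] * (V - EK);
  double IKur = P.gKurS * r[25] * s[6] * s[6] * s[6] * s[7] * (V - EK);
  double IKr  = P.gKr * r[26] * s[8] * (V - EK);
  double IKs  = P.gKs * s[9] * s[9] * (V - EK);
  double ICaL = P.gCaL * s[10] * s[11] * s[12] * (V - 65.0);
  double INaK = P.INaK * r[27] / (1.0 + std::pow(KmNai / s[16], 1.5))
                * (K_o / (K_o + KmKo));
  double Nai3 = s[16] * s[16] * s[16];
  double INaCa = P.INaCa * (r[28] * Nai3 * Ca_o - r[29] * Na_o * Na_o * Na_o * s[18])
                / ((KmNa3 + Na_o * Na_o * Na_o) * (KmCa + Ca_o)
                   * (1.0 + Ksat * r[29]));
  double IbNa = P.gbNa * (V - ENa);
  double IbCa = P.gbCa * (V - ECa);
  double IpCa = P.IpCa * s[18] / (0.0005 + s[18]);
  double IKACh = P.gAChD * r[30] * (V - EK);
  double Itot = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa + INaK
              + INaCa + IbNa + IbCa + IKACh;
  NumericVector out = NumericVector::create(
    _["I_Na"] = INa, _["I_K1"] = IK1, _["I_to"] = Ito, _["I_Kur"] = IKur,
    _["I_Kr"] = IKr, _["I_Ks"] = IKs, _["I_CaL"] = ICaL, _["I_NaK"] = INaK,
    _["I_NaCa"] = INaCa, _["I_bNa"] = IbNa, _["I_bCa"] = IbCa,
    _["I_pCa"] = IpCa, _["I_KACh"] = IKACh, _["I_total"] = Itot);
  return out;
}

// Exact single forward-Euler step (used by step_cell and its tests).
// [[Rcpp::export]]
NumericVector cpp_step_cell_exact(NumericVector state, NumericVector params,
                                  double istim, double dt) {
  if (state.size() != 21) stop("state must have 21 elements");
  arma::vec p(params.begin(), params.size());
  Pars P(p);
  NumericVector out = clone(state);
  double r[NTAB];
  vrates(out[0], r);
  cell_euler(out.begin(), r, P, istim, dt, nullptr);
  return out;
}

// Kneller I_KACh at a given voltage/E_K/ACh (exact; for tests and docs).
// [[Rcpp::export]]
double cpp_ikach(double V, double EK, double ach_nM) {
  double r[NTAB];
  vrates(V, r);
  return kach_dose(ach_nM) * r[30] * (V - EK);
}

// Build the voltage lookup table used by the steppers.
static arma::mat build_tables(double vmin, double vmax, double dv, int& nv) {
  nv = (int)std::ceil((vmax - vmin) / dv) + 1;
  arma::mat T(NTAB, nv);
  double r[NTAB];
  for (int i = 0; i < nv; ++i) {
    vrates(vmin + i * dv, r);
    for (int q = 0; q < NTAB; ++q) T(q, i) = r[q];
  }
  return T;
}

// Monodomain time loop shared by single-cell, strand and sheet runs.
//
// state:  21 x ncells matrix (modified copy returned)
// Px, Py: dense diffusion propagators per axis (empty matrix = no diffusion
//         along that axis); cells indexed as ix + nx*iy
// stim_*: parallel vectors describing rectangular current pulses; amplitude
//         is in pA/pF and is applied with depolarizing sign (dV/dt += amp)
// masks:  list of 0-based node index vectors
// movie_stride: record V every movie_stride steps (0 = off), from
//         movie_start_step; probes: 0-based node indices recorded at full dt
// track_peaks: track per-node peak |I| of I_Na, I_to, I_Kur, I_CaL from
//         peaks_start_step; split Strang steps when strang = true
// [[Rcpp::export]]
List cpp_run_tissue(arma::mat state, arma::mat Px, arma::mat Py,
                    int nx, int ny, double dt, int nsteps, double t0,
                    NumericVector stim_onset, NumericVector stim_dur,
                    NumericVector stim_amp, IntegerVector stim_mask,
                    List masks, NumericVector params,
                    int movie_stride, int movie_start_step,
                    IntegerVector probes, bool track_peaks,
                    int peaks_start_step, bool strang,
                    bool record_probe_currents) {
  const int ncells = state.n_cols;
  if ((int)state.n_rows != 21) stop("state must be 21 x ncells");
  if (nx * ny != ncells) stop("grid dims inconsistent with state");
  arma::vec p(params.begin(), params.size());
  Pars P(p);

  const double VMIN = -120.0, VMAX = 80.0, DV = 0.005;
  int nv;
  arma::mat T = build_tables(VMIN, VMAX, DV, nv);
  const double inv_dv = 1.0 / DV;

  const bool use_x = Px.n_rows > 0, use_y = Py.n_rows > 0;
  if (use_x && (int)Px.n_rows != nx) stop("Px dimension mismatch");
  if (use_y && (int)Py.n_rows != ny) stop("Py dimension mismatch");
  arma::mat Px_h, Py_h; // half-step propagators for Strang splitting
  if (strang) {
    if (use_x) Px_h = arma::real(arma::sqrtmat(Px));
    if (use_y) Py_h = arma::real(arma::sqrtmat(Py));
  }

  const int nstim = stim_onset.size();
  std::vector<std::vector<int>> mask_idx(masks.size());
  for (int i = 0; i < masks.size(); ++i) {
    IntegerVector m = masks[i];
    mask_idx[i].assign(m.begin(), m.end());
  }

  // recording buffers
  int nframes = 0;
  if (movie_stride > 0)
    nframes = (nsteps - movie_start_step) / movie_stride + 1;
  arma::mat movie(movie_stride > 0 ? ncells : 0, nframes);
  arma::vec movie_t(nframes);
  const int nprobe = probes.size();
  arma::mat probe_v(nsteps + 1, nprobe);
  arma::mat probe_cur; // I_Na, I_to, I_Kur, I_CaL per probe, full dt
  if (record_probe_currents) probe_cur.zeros(nsteps + 1, 4 * nprobe);
  arma::mat peaks(4, track_peaks ? ncells : 0, arma::fill::zeros);

  arma::vec istim(ncells, arma::fill::zeros);
  double gate_min = 1.0, gate_max = 0.0;
  int frame = 0;
  std::string error_msg = "";
  int abort_step = -1;

  // record initial probe samples
  for (int q = 0; q < nprobe; ++q) probe_v(0, q) = state(0, probes[q]);
  if (record_probe_currents) {
    for (int q = 0; q < nprobe; ++q) {
      // exact currents at t0 (cheap, once)
      NumericVector st(21);
      for (int k = 0; k < 21; ++k) st[k] = state(k, probes[q]);
      NumericVector cur = cpp_ionic_currents(st, params);
      probe_cur(0, 4 * q + 0) = cur["I_Na"];
      probe_cur(0, 4 * q + 1) = cur["I_to"];
      probe_cur(0, 4 * q + 2) = cur["I_Kur"];
      probe_cur(0, 4 * q + 3) = cur["I_CaL"];
    }
  }
  if (movie_stride > 0 && movie_start_step == 0) {
    movie.col(frame) = state.row(0).t();
    movie_t(frame) = t0;
    ++frame;
  }

  arma::vec rloc(NTAB);
  for (int step = 0; step < nsteps; ++step) {
    const double t = t0 + step * dt;

    // stimulus currents active over [onset, onset + dur)
    istim.zeros();
    bool any_stim = false;
    for (int e = 0; e < nstim; ++e) {
      if (t >= stim_onset[e] - 1e-9 && t < stim_onset[e] + stim_dur[e] - 1e-9) {
        const std::vector<int>& mi = mask_idx[stim_mask[e]];
        for (size_t k = 0; k < mi.size(); ++k) istim[mi[k]] -= stim_amp[e];
        any_stim = true;
      }
    }

    if (strang) { // half diffusion step first
      if (use_x || use_y) {
        arma::rowvec Vr = state.row(0);
        arma::mat Vm(Vr.memptr(), nx, ny, false, true);
        arma::mat Vnew = Vm;
        if (use_x) Vnew = Px_h * Vnew;
        if (use_y) Vnew = Vnew * Py_h.t();
        state.row(0) = arma::rowvec(Vnew.memptr(), ncells);
      }
    }

    // reaction substep (forward Euler, all cells)
    for (int c = 0; c < ncells; ++c) {
      double* s = state.colptr(c);
      double V = s[0];
      if (!R_finite(V) || std::fabs(V) > 200.0) {
        error_msg = "instability: |V| > 200 mV";
        abort_step = step;
        break;
      }
      double vv = (V - VMIN) * inv_dv;
      if (vv < 0.0) vv = 0.0;
      if (vv > nv - 1.001) vv = nv - 1.001;
      int i0 = (int)vv;
      double w = vv - i0;
      const double* c0 = T.colptr(i0);
      const double* c1 = T.colptr(i0 + 1);
      double r[NTAB];
      for (int q = 0; q < NTAB; ++q) r[q] = c0[q] * (1.0 - w) + c1[q] * w;
      double itot;
      cell_euler(s, r, P, istim[c], dt, &itot);
      if (track_peaks && step >= peaks_start_step) {
        // recompute the four tracked currents from the pre-step V and gates
        // is not needed: track from the state just used (V before update)
        const double EK  = RTF * std::log(K_o / s[17]);
        const double ENa = RTF * std::log(Na_o / s[16]);
        // gates already advanced one Euler step; at dt = 0.01 ms the
        // difference is far below the per-node peak resolution of interest
        double INa  = P.gNa * s[1] * s[1] * s[1] * s[2] * s[3] * (V - ENa);
        double Ito  = P.gto * s[4] * s[4] * s[4] * s[5] * (V - EK);
        double IKur = P.gKurS * r[25] * s[6] * s[6] * s[6] * s[7] * (V - EK);
        double ICaL = P.gCaL * s[10] * s[11] * s[12] * (V - 65.0);
        if (std::fabs(INa)  > peaks(0, c)) peaks(0, c) = std::fabs(INa);
        if (std::fabs(Ito)  > peaks(1, c)) peaks(1, c) = std::fabs(Ito);
        if (std::fabs(IKur) > peaks(2, c)) peaks(2, c) = std::fabs(IKur);
        if (std::fabs(ICaL) > peaks(3, c)) peaks(3, c) = std::fabs(ICaL);
      }
      // gate-range monitoring (indices 1..15)
      for (int g = 1; g <= 15; ++g) {
        if (s[g] < gate_min) gate_min = s[g];
        if (s[g] > gate_max) gate_max = s[g];
      }
    }
    if (abort_step >= 0) break;

    // diffusion substep on V only
    if (use_x || use_y) {
      arma::rowvec Vr = state.row(0);
      arma::mat Vm(Vr.memptr(), nx, ny, false, true);
      arma::mat Vnew = Vm;
      if (strang) {
        if (use_x) Vnew = Px_h * Vnew;
        if (use_y) Vnew = Vnew * Py_h.t();
      } else {
        if (use_x) Vnew = Px * Vnew;
        if (use_y) Vnew = Vnew * Py.t();
      }
      state.row(0) = arma::rowvec(Vnew.memptr(), ncells);
    }

    // recording
    for (int q = 0; q < nprobe; ++q) probe_v(step + 1, q) = state(0, probes[q]);
    if (record_probe_currents) {
      for (int q = 0; q < nprobe; ++q) {
        NumericVector st(21);
        for (int k = 0; k < 21; ++k) st[k] = state(k, probes[q]);
        NumericVector cur = cpp_ionic_currents(st, params);
        probe_cur(step + 1, 4 * q + 0) = cur["I_Na"];
        probe_cur(step + 1, 4 * q + 1) = cur["I_to"];
        probe_cur(step + 1, 4 * q + 2) = cur["I_Kur"];
        probe_cur(step + 1, 4 * q + 3) = cur["I_CaL"];
      }
    }
    if (movie_stride > 0 && step + 1 >= movie_start_step
        && (step + 1 - movie_start_step) % movie_stride == 0
        && frame < nframes) {
      movie.col(frame) = state.row(0).t();
      movie_t(frame) = t0 + (step + 1) * dt;
      ++frame;
    }
    (void)any_stim;
  }

  if (frame > 0 && frame < (int)movie.n_cols) movie = movie.cols(0, frame - 1);
  return List::create(
    _["state"] = state,
    _["movie"] = movie,
    _["movie_times"] = frame > 0 ? movie_t.subvec(0, frame - 1) : arma::vec(),
    _["n_frames"] = frame,
    _["probe_v"] = probe_v,
    _["probe_currents"] = probe_cur,
    _["peaks"] = peaks,
    _["gate_min"] = gate_min,
    _["gate_max"] = gate_max,
    _["error"] = error_msg,
    _["abort_step"] = abort_step);
}
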