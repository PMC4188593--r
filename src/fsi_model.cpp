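// Single-compartment fast-spiking interneuron model.
//
// Currents: transient Na+ (instantaneous activation m_inf^3, inactivation h),
// Kv3-like delayed rectifier (n^2), Kv1-like D-current (activation a, slow
// inactivation b), ohmic leak.  Units: mV, ms, pA, nS, pF.
//
// Classic RK4 at a fixed step; additive current noise is drawn once per step
// and held constant across the four stages, so the noiseless path is pure RK4.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double gam(double v, double th, double sig) {
  return 1.0 / (1.0 + std::exp(-(v - th) / sig));
}

struct Membrane {
  double Cm, gL, gNa, gKv3, gKd, gAd, EL, ENa, EK;
  // gating constants
  double th_m, sig_m;
  double th_h, sig_h, tauh0, tauh1, tauh_th, tauh_sig;
  double th_n, sig_n, taun0, taun1, taunA_th, taunA_sig, taunB_th, taunB_sig;
  double th_a, sig_a, tau_a;
  double th_b, sig_b, tau_b, b_min;
  double th_z, sig_z, tau_z;   // slow spike-activated adaptation K+ gate
};

static Membrane unpack(const NumericVector& p, const NumericVector& k) {
  Membrane m;
  m.Cm = p[0]; m.gL = p[1]; m.gNa = p[2]; m.gKv3 = p[3]; m.gKd = p[4];
  m.gAd = p[5]; m.EL = p[6]; m.ENa = p[7]; m.EK = p[8];
  m.th_m = k[0];  m.sig_m = k[1];
  m.th_h = k[2];  m.sig_h = k[3];
  m.tauh0 = k[4]; m.tauh1 = k[5]; m.tauh_th = k[6]; m.tauh_sig = k[7];
  m.th_n = k[8];  m.sig_n = k[9];
  m.taun0 = k[10]; m.taun1 = k[11];
  m.taunA_th = k[12]; m.taunA_sig = k[13];
  m.taunB_th = k[14]; m.taunB_sig = k[15];
  m.th_a = k[16]; m.sig_a = k[17]; m.tau_a = k[18];
  m.th_b = k[19]; m.sig_b = k[20]; m.tau_b = k[21]; m.b_min = k[22];
  m.th_z = k[23]; m.sig_z = k[24]; m.tau_z = k[25];
  return m;
}

// y = {V, h, n, a, b, z}
static inline void deriv(const Membrane& m, const double* y, double Iin,
                         double* dy) {
  const double V = y[0], h = y[1], n = y[2], a = y[3], b = y[4], z = y[5];
  const double minf = gam(V, m.th_m, m.sig_m);
  const double INa  = m.gNa * minf * minf * minf * h * (V - m.ENa);
  const double IK3  = m.gKv3 * n * n * (V - m.EK);
  const double IKd  = m.gKd * a * b * (V - m.EK);
  const double IAd  = m.gAd * z * (V - m.EK);
  const double IL   = m.gL * (V - m.EL);
  dy[0] = (Iin - IL - INa - IK3 - IKd - IAd) / m.Cm;

  const double hinf = gam(V, m.th_h, m.sig_h);
  const double tauh = m.tauh0 + m.tauh1 * gam(V, m.tauh_th, m.tauh_sig);
  dy[1] = (hinf - h) / tauh;

  const double ninf = gam(V, m.th_n, m.sig_n);
  const double taun = (m.taun0 + m.taun1 * gam(V, m.taunA_th, m.taunA_sig)) *
                      (m.taun0 + m.taun1 * gam(V, m.taunB_th, m.taunB_sig));
  dy[2] = (ninf - n) / taun;

  dy[3] = (gam(V, m.th_a, m.sig_a) - a) / m.tau_a;
  dy[4] = (m.b_min + (1.0 - m.b_min) * gam(V, m.th_b, m.sig_b) - b) / m.tau_b;
  dy[5] = (gam(V, m.th_z, m.sig_z) - z) / m.tau_z;
}

// [[Rcpp::export(name = ".simulate_fsi_cpp")]]
NumericVector simulate_fsi_cpp(NumericVector pars, NumericVector kin,
                               NumericVector stim, double dt, double v0,
                               double noise_sigma, int thin) {
  const Membrane m = unpack(pars, kin);
  const int nstep = stim.size();
  const int nout = nstep / thin;
  NumericVector out(nout);

  double y[6], k1[6], k2[6], k3[6], k4[6], yt[6];
  y[0] = v0;
  y[1] = gam(v0, m.th_h, m.sig_h);
  y[2] = gam(v0, m.th_n, m.sig_n);
  y[3] = gam(v0, m.th_a, m.sig_a);
  y[4] = m.b_min + (1.0 - m.b_min) * gam(v0, m.th_b, m.sig_b);
  y[5] = gam(v0, m.th_z, m.sig_z);

  int j = 0;
  for (int i = 0; i < nstep; ++i) {
    if (i % thin == 0) out[j++] = y[0];
    double Iin = stim[i];
    if (noise_sigma > 0.0) Iin += noise_sigma * norm_rand();

    deriv(m, y, Iin, k1);
    for (int s = 0; s < 6; ++s) yt[s] = y[s] + 0.5 * dt * k1[s];
    deriv(m, yt, Iin, k2);
    for (int s = 0; s < 6; ++s) yt[s] = y[s] + 0.5 * dt * k2[s];
    deriv(m, yt, Iin, k3);
    for (int s = 0; s < 6; ++s) yt[s] = y[s] + dt * k3[s];
    deriv(m, yt, Iin, k4);
    for (int s = 0; s < 6; ++s)
      y[s] += dt / 6.0 * (k1[s] + 2.0 * k2[s] + 2.0 * k3[s] + k4[s]);

    if (!std::isfinite(y[0]))
      stop("non-finite membrane potential at t = %.3f ms", (i + 1) * dt);
  }
  return out;
}

// Steady-state total membrane current at voltage V with gates at their
// steady-state values; used to calibrate the leak reversal for a target
// resting potential.
// [[Rcpp::export(name = ".fsi_steady_current_cpp")]]
double fsi_steady_current_cpp(NumericVector pars, NumericVector kin, double V) {
  const Membrane m = unpack(pars, kin);
  double y[6] = {V, gam(V, m.th_h, m.sig_h), gam(V, m.th_n, m.sig_n),
                 gam(V, m.th_a, m.sig_a),
                 m.b_min + (1.0 - m.b_min) * gam(V, m.th_b, m.sig_b),
                 gam(V, m.th_z, m.sig_z)};
  double dy[6];
  deriv(m, y, 0.0, dy);
  return -dy[0] * m.Cm;  // net outward current at V (pA)
}
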