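#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Lumped two-mass vocal-fold model, symmetric reference configuration scaled
// per side. Unit system: g / cm / ms (so 0.008 pressure units = 800 Pa).
//
// State layout (8 doubles): x[l1], x[l2], x[r1], x[r2], v[l1], v[l2], v[r1], v[r2]
// Mass index convention: 0=(left,lower) 1=(left,upper) 2=(right,lower) 3=(right,upper)

struct TwoMassSystem {
  double m[4];   // masses (g)
  double k[4];   // anchor stiffness (g/ms^2)
  double r[4];   // damping (g/ms)
  double c[4];   // collision stiffness (g/ms^2)
  double kc;     // vertical coupling stiffness (g/ms^2), shared
  double a01, a02;  // rest areas (cm^2)
  double d1;        // lower plate thickness (cm)
  double L;         // fold length (cm)
  double Ps;        // subglottal pressure (g cm^-1 ms^-2)
};

// Forces on the four masses for a given state. Left and right sides use
// textually identical expressions so that symmetric configurations produce
// bitwise-identical trajectories.
static inline void forces(const TwoMassSystem& p, const double* s, double* F) {
  const double xl1 = s[0], xl2 = s[1], xr1 = s[2], xr2 = s[3];
  const double vl1 = s[4], vl2 = s[5], vr1 = s[6], vr2 = s[7];

  const double a1 = p.a01 + p.L * (xl1 + xr1);
  const double a2 = p.a02 + p.L * (xl2 + xr2);
  const double amin = std::min(a1, a2);

  // Bernoulli driving pressure acts on the lower masses only; pressure
  // recovers to zero at the narrowest open section. Closed lower plane
  // (a1 <= 0) shields the folds from the subglottal pressure entirely;
  // closed upper plane with open lower plane exposes the full pressure.
  double Pd = 0.0;
  if (a1 > 0.0) Pd = (amin > 0.0) ? p.Ps * (1.0 - (amin / a1) * (amin / a1)) : p.Ps;
  const double Fd = Pd * p.L * p.d1;

  // anchor spring + damping
  F[0] = -p.k[0] * xl1 - p.r[0] * vl1;
  F[1] = -p.k[1] * xl2 - p.r[1] * vl2;
  F[2] = -p.k[2] * xr1 - p.r[2] * vr1;
  F[3] = -p.k[3] * xr2 - p.r[3] * vr2;

  // vertical coupling within each side
  F[0] += -p.kc * (xl1 - xl2);
  F[1] += -p.kc * (xl2 - xl1);
  F[2] += -p.kc * (xr1 - xr2);
  F[3] += -p.kc * (xr2 - xr1);

  // collision: restoring force proportional to penetration a_i/(2L), active
  // only for negative glottal area (contact); a_i = 0 counts as open
  if (a1 < 0.0) {
    F[0] += -p.c[0] * a1 / (2.0 * p.L);
    F[2] += -p.c[2] * a1 / (2.0 * p.L);
  }
  if (a2 < 0.0) {
    F[1] += -p.c[1] * a2 / (2.0 * p.L);
    F[3] += -p.c[3] * a2 / (2.0 * p.L);
  }

  F[0] += Fd;
  F[2] += Fd;
}

static inline void deriv(const TwoMassSystem& p, const double* s, double* ds) {
  double F[4];
  forces(p, s, F);
  ds[0] = s[4]; ds[1] = s[5]; ds[2] = s[6]; ds[3] = s[7];
  ds[4] = F[0] / p.m[0];
  ds[5] = F[1] / p.m[1];
  ds[6] = F[2] / p.m[2];
  ds[7] = F[3] / p.m[3];
}

static inline void rk4_step(const TwoMassSystem& p, double* s, double dt) {
  double k1[8], k2[8], k3[8], k4[8], tmp[8];
  deriv(p, s, k1);
  for (int j = 0; j < 8; ++j) tmp[j] = s[j] + 0.5 * dt * k1[j];
  deriv(p, tmp, k2);
  for (int j = 0; j < 8; ++j) tmp[j] = s[j] + 0.5 * dt * k2[j];
  deriv(p, tmp, k3);
  for (int j = 0; j < 8; ++j) tmp[j] = s[j] + dt * k3[j];
  deriv(p, tmp, k4);
  for (int j = 0; j < 8; ++j)
    s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
}

static TwoMassSystem build_system(NumericVector q, List params) {
  TwoMassSystem p;
  const double m1 = params["m1"], m2 = params["m2"];
  const double k1 = params["k1"], k2 = params["k2"];
  const double r1 = params["r1"], r2 = params["r2"];
  const double cf = params["c_factor"];
  const double Qml = q[0], Qmr = q[1], Qkl = q[2], Qkr = q[3], QPs = q[4], Qkc = q[5];

  p.m[0] = Qml * m1; p.m[1] = Qml * m2;
  p.m[2] = Qmr * m1; p.m[3] = Qmr * m2;
  p.k[0] = Qkl * k1; p.k[1] = Qkl * k2;
  p.k[2] = Qkr * k1; p.k[3] = Qkr * k2;
  p.r[0] = r1; p.r[1] = r2; p.r[2] = r1; p.r[3] = r2;
  for (int j = 0; j < 4; ++j) p.c[j] = (1.0 + Qkc) * cf * p.k[j];
  p.kc  = as<double>(params["kc"]);
  p.a01 = as<double>(params["a01"]);
  p.a02 = as<double>(params["a02"]);
  p.d1  = as<double>(params["d1"]);
  p.L   = as<double>(params["L"]);
  p.Ps  = QPs * as<double>(params["Ps_ref"]);
  return p;
}

// [[Rcpp::export(name = ".cpp_simulate_twomass")]]
List cpp_simulate_twomass(NumericVector q, List params, double fs, int n_samples,
                          double transient_ms, int oversample,
                          NumericVector init_x, bool return_state) {
  TwoMassSystem p = build_system(q, params);

  const double dt = 1000.0 / (fs * oversample);  // ms per substep
  double s[8] = { init_x[0], init_x[1], init_x[2], init_x[3], 0.0, 0.0, 0.0, 0.0 };

  // transient: integrate in whole output-sample intervals so the recorded
  // grid is unaffected by transient_ms rounding
  const int n_trans = (int)std::ceil(transient_ms * fs / 1000.0);
  bool ok = true;

  NumericVector left(n_samples), right(n_samples);
  NumericMatrix state;
  if (return_state) state = NumericMatrix(n_samples, 8);

  for (int n = 0; n < n_trans + n_samples && ok; ++n) {
    if (n >= n_trans) {
      const int i = n - n_trans;
      left[i] = s[0];
      right[i] = s[2];
      if (return_state)
        for (int j = 0; j < 8; ++j) state(i, j) = s[j];
    }
    for (int sub = 0; sub < oversample; ++sub) rk4_step(p, s, dt);
    for (int j = 0; j < 8; ++j)
      if (!std::isfinite(s[j]) || std::fabs(s[j]) > 100.0) { ok = false; break; }
  }

  List out = List::create(_["left"] = left, _["right"] = right,
                          _["fs"] = fs, _["ok"] = ok);
  if (return_state) out["state"] = state;
  return out;
}

// Instantaneous force decomposition at a given state; used for diagnostic
// force accounting (e.g. verifying zero collision force while open).
// [[Rcpp::export(name = ".cpp_twomass_forces")]]
NumericMatrix cpp_twomass_forces(NumericVector q, List params, NumericVector state) {
  TwoMassSystem p = build_system(q, params);
  double s[8];
  for (int j = 0; j < 8; ++j) s[j] = state[j];

  NumericMatrix out(4, 4);  // rows: masses l1,l2,r1,r2; cols: anchor, coupling, collision, driving
  const double xl1 = s[0], xl2 = s[1], xr1 = s[2], xr2 = s[3];
  const double vl1 = s[4], vl2 = s[5], vr1 = s[6], vr2 = s[7];
  const double a1 = p.a01 + p.L * (xl1 + xr1);
  const double a2 = p.a02 + p.L * (xl2 + xr2);
  const double amin = std::min(a1, a2);
  double Pd = 0.0;
  if (a1 > 0.0) Pd = (amin > 0.0) ? p.Ps * (1.0 - (amin / a1) * (amin / a1)) : p.Ps;

  out(0, 0) = -p.k[0] * xl1 - p.r[0] * vl1;
  out(1, 0) = -p.k[1] * xl2 - p.r[1] * vl2;
  out(2, 0) = -p.k[2] * xr1 - p.r[2] * vr1;
  out(3, 0) = -p.k[3] * xr2 - p.r[3] * vr2;
  out(0, 1) = -p.kc * (xl1 - xl2);
  out(1, 1) = -p.kc * (xl2 - xl1);
  out(2, 1) = -p.kc * (xr1 - xr2);
  out(3, 1) = -p.kc * (xr2 - xr1);
  if (a1 < 0.0) { out(0, 2) = -p.c[0] * a1 / (2.0 * p.L); out(2, 2) = -p.c[2] * a1 / (2.0 * p.L); }
  if (a2 < 0.0) { out(1, 2) = -p.c[1] * a2 / (2.0 * p.L); out(3, 2) = -p.c[3] * a2 / (2.0 * p.L); }
  out(0, 3) = Pd * p.L * p.d1;
  out(2, 3) = Pd * p.L * p.d1;
  return out;
}
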