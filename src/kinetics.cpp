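#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Flat parameter layout shared with R (see .lr_par_order in R/kinetic_model.R):
// vs C0 v2 ks a2 d1 d2 d5 v1 c1 tau p0 vp kp
enum { VS, C0_, V2, KS, A2, D1, D2, D5, V1, C1, TAU, P0_, VP, KP, NPAR };

static inline void lr_deriv(const double* s, const double* p, double* d) {
  const double c = s[0], q = s[1], ip3 = s[2];
  const double cer = (p[C0_] * (1.0 + p[C1]) - c) / p[C1];
  const double hp = ip3 / (ip3 + p[D1]);
  const double hc = c / (c + p[D5]);
  const double jc = p[V1] * hp * hp * hp * hc * hc * hc * q * q * q * (cer - c);
  const double js = p[VS] * c * c / (c * c + p[KS] * p[KS]);
  const double jl = p[V2] * (cer - c);
  d[0] = jc - js + jl;
  d[1] = p[A2] * p[D2] * (ip3 + p[D1]) / (ip3 + p[D2]) * (1.0 - q) - p[A2] * c * q;
  d[2] = -(ip3 - p[P0_]) / p[TAU] + p[VP] * (c + 0.2 * p[KP]) / (c + p[KP]);
}

// Post-step safeguarding: keep c in (0, C0*(1+c1)), q in [0,1], p > 0.
static inline int clamp_state(double* s, const double* p) {
  const double eps = 1e-9;
  const double cmax = p[C0_] * (1.0 + p[C1]) - eps;
  int n = 0;
  if (s[0] < eps) { s[0] = eps; ++n; } else if (s[0] > cmax) { s[0] = cmax; ++n; }
  if (s[1] < 0.0) { s[1] = 0.0; ++n; } else if (s[1] > 1.0) { s[1] = 1.0; ++n; }
  if (s[2] < eps) { s[2] = eps; ++n; }
  return n;
}

// Explicit Euler micro-stepping across one acquisition frame.
static int evolve_one(double* s, const double* p, double frame_dt, double micro_dt) {
  const int nsub = (int)std::lround(frame_dt / micro_dt);
  double d[3];
  int clamps = 0;
  for (int i = 0; i < nsub; ++i) {
    lr_deriv(s, p, d);
    s[0] += micro_dt * d[0];
    s[1] += micro_dt * d[1];
    s[2] += micro_dt * d[2];
    clamps += clamp_state(s, p);
  }
  return clamps;
}

// [[Rcpp::export]]
NumericVector lr_deriv_cpp(NumericVector state, NumericVector params) {
  double d[3];
  lr_deriv(REAL(state), REAL(params), d);
  return NumericVector::create(d[0], d[1], d[2]);
}

// [[Rcpp::export]]
List lr_evolve_cpp(NumericVector state, NumericVector params,
                   double frame_dt, double micro_dt) {
  double s[3] = { state[0], state[1], state[2] };
  int clamps = 0;
  if (frame_dt > 0.0) clamps = evolve_one(s, REAL(params), frame_dt, micro_dt);
  return List::create(_["state"] = NumericVector::create(s[0], s[1], s[2]),
                      _["clamps"] = clamps);
}

// States at frames 0, 1, ..., n_frames-1 (row 0 is the initial state).
// [[Rcpp::export]]
List lr_simulate_cpp(NumericVector state0, NumericVector params,
                     int n_frames, double frame_dt, double micro_dt) {
  NumericMatrix out(n_frames, 3);
  double s[3] = { state0[0], state0[1], state0[2] };
  int clamps = 0;
  out(0, 0) = s[0]; out(0, 1) = s[1]; out(0, 2) = s[2];
  for (int t = 1; t < n_frames; ++t) {
    clamps += evolve_one(s, REAL(params), frame_dt, micro_dt);
    out(t, 0) = s[0]; out(t, 1) = s[1]; out(t, 2) = s[2];
  }
  return List::create(_["states"] = out, _["clamps"] = clamps);
}

// Advance each row of `states` by one frame; used for parameter Jacobians.
// [[Rcpp::export]]
NumericMatrix lr_evolve_batch_cpp(NumericMatrix states, NumericVector params,
                                  double frame_dt, double micro_dt) {
  const int n = states.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double s[3] = { states(i, 0), states(i, 1), states(i, 2) };
    evolve_one(s, REAL(params), frame_dt, micro_dt);
    out(i, 0) = s[0]; out(i, 1) = s[1]; out(i, 2) = s[2];
  }
  return out;
}

// Central finite-difference Jacobian of the one-frame transition wrt the state.
// [[Rcpp::export]]
NumericMatrix lr_evolve_jac_cpp(NumericVector state, NumericVector params,
                                double frame_dt, double micro_dt) {
  NumericMatrix J(3, 3);
  const double* p = REAL(params);
  for (int j = 0; j < 3; ++j) {
    const double h = 1e-6 * std::max(1.0, std::fabs(state[j]));
    double sp[3] = { state[0], state[1], state[2] };
    double sm[3] = { state[0], state[1], state[2] };
    sp[j] += h; sm[j] -= h;
    evolve_one(sp, p, frame_dt, micro_dt);
    evolve_one(sm, p, frame_dt, micro_dt);
    for (int i = 0; i < 3; ++i) J(i, j) = (sp[i] - sm[i]) / (2.0 * h);
  }
  return J;
}
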