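// Two-channel Go/NoGo basal-ganglia firing-rate network.
//
// Each unit is a first-order low-pass filter feeding a sigmoid:
//   tau * dy/dt = -y + sigma(u),   sigma(u) = 1 / (1 + exp(-a * (u - u0)))
// integrated with explicit Euler at dt << tau.  State layout (13 units):
//   [M1 M2 G1 G2 N1 N2 E1 E2 I1 I2 Th1 Th2 Ch]
// M: motor cortex, G: Go striatum, N: NoGo striatum, E: GPe, I: GPi/SNr,
// Th: thalamus, Ch: shared cholinergic interneuron.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct BgParams {
  double tau, dt, a, u0;
  double wL, wThM, wMTh;
  double gGo, gNoGo;  // cortico-striatal base gains, scaled by the synapse set
  double wGoGPi, wNoGoGPe, wGPeGPi, wGPiTh, wChNoGo;
  double tonicGPe, tonicGPi, tonicCh;
  double alphaGo, betaNoGo, kChD;
  double stim_amp, tap_threshold, timeout, lag;
};

BgParams unpack(const NumericVector& p) {
  BgParams q;
  q.tau = p["tau_ms"];       q.dt = p["dt_ms"];
  q.a = p["sig_a"];          q.u0 = p["sig_u0"];
  q.gGo = p["gGo"];          q.gNoGo = p["gNoGo"];
  q.wL = p["wL"];            q.wThM = p["wThM"];      q.wMTh = p["wMTh"];
  q.wGoGPi = p["wGoGPi"];    q.wNoGoGPe = p["wNoGoGPe"];
  q.wGPeGPi = p["wGPeGPi"];  q.wGPiTh = p["wGPiTh"];  q.wChNoGo = p["wChNoGo"];
  q.tonicGPe = p["tonicGPe"]; q.tonicGPi = p["tonicGPi"]; q.tonicCh = p["tonicCh"];
  q.alphaGo = p["alphaGo"];  q.betaNoGo = p["betaNoGo"]; q.kChD = p["kChD"];
  q.stim_amp = p["stim_amp"]; q.tap_threshold = p["tap_threshold"];
  q.timeout = p["timeout_ms"]; q.lag = p["lag_ms"];
  return q;
}

inline double sig(double u, double a, double u0) {
  return 1.0 / (1.0 + std::exp(-a * (u - u0)));
}

// One Euler step in place.  stim: length-2 external drive to motor cortex.
inline void euler_step(double* y, const BgParams& q,
                       const double* wGo, const double* wNoGo,
                       const double* stim, double D) {
  const double* M = y;       const double* G = y + 2;  const double* N = y + 4;
  const double* E = y + 6;   const double* I = y + 8;  const double* Th = y + 10;
  const double Ch = y[12];
  const double gden = M[0] + M[1] + 1e-9;
  double tgt[13];
  for (int i = 0; i < 2; ++i) {
    const int j = 1 - i;
    const double gate = M[i] / gden;  // D excites only the dominant Go channel
    tgt[i]      = sig(stim[i] + q.wThM * Th[i] - q.wL * M[j], q.a, q.u0);
    tgt[2 + i]  = sig(q.gGo * wGo[i] * M[i] + q.alphaGo * D * gate, q.a, q.u0);
    tgt[4 + i]  = sig(q.gNoGo * wNoGo[i] * M[i] - q.betaNoGo * D + q.wChNoGo * Ch, q.a, q.u0);
    tgt[6 + i]  = sig(q.tonicGPe - q.wNoGoGPe * N[i], q.a, q.u0);
    tgt[8 + i]  = sig(q.tonicGPi - q.wGoGPi * G[i] - q.wGPeGPi * E[i], q.a, q.u0);
    tgt[10 + i] = sig(q.wMTh * M[i] - q.wGPiTh * I[i], q.a, q.u0);
  }
  tgt[12] = sig(q.tonicCh - q.kChD * D, q.a, q.u0);
  const double r = q.dt / q.tau;
  for (int k = 0; k < 13; ++k) y[k] += r * (-y[k] + tgt[k]);
}

} // namespace

// [[Rcpp::export(name = ".bg_run_cpp")]]
NumericMatrix bg_run_cpp(NumericVector params, NumericVector state,
                         NumericVector wGo, NumericVector wNoGo,
                         NumericVector stim, double D, double duration_ms,
                         double record_every_ms) {
  BgParams q = unpack(params);
  double y[13];
  for (int k = 0; k < 13; ++k) y[k] = state[k];
  const int nstep = (int)std::round(duration_ms / q.dt);
  const int rec = record_every_ms > 0
      ? std::max(1, (int)std::round(record_every_ms / q.dt)) : nstep;
  const int nout = nstep / rec + 1;
  NumericMatrix out(nout, 14);
  int row = 0;
  out(row, 0) = 0.0;
  for (int k = 0; k < 13; ++k) out(row, k + 1) = y[k];
  ++row;
  double st[2] = { stim[0], stim[1] };
  for (int s = 1; s <= nstep; ++s) {
    euler_step(y, q, &wGo[0], &wNoGo[0], st, D);
    if (s % rec == 0 && row < nout) {
      out(row, 0) = s * q.dt;
      for (int k = 0; k < 13; ++k) out(row, k + 1) = y[k];
      ++row;
    }
  }
  return out(Range(0, row - 1), Range(0, 13));
}

// Run with stimulus on channel `cue` (0/1) until that channel's motor unit
// crosses tap_threshold from below, or timeout.  Returns latency (ms, = timeout
// if no crossing), selected flag and final state.
// [[Rcpp::export(name = ".bg_select_cpp")]]
List bg_select_cpp(NumericVector params, NumericVector state,
                   NumericVector wGo, NumericVector wNoGo,
                   int cue, NumericVector stim_noise, double D) {
  BgParams q = unpack(params);
  double y[13];
  for (int k = 0; k < 13; ++k) y[k] = state[k];
  double st[2] = { stim_noise[0], stim_noise[1] };
  st[cue] += q.stim_amp;
  const int nstep = (int)std::round(q.timeout / q.dt);
  double latency = q.timeout;
  int selected = -1;
  bool below = y[cue] < q.tap_threshold;
  for (int s = 1; s <= nstep; ++s) {
    euler_step(y, q, &wGo[0], &wNoGo[0], st, D);
    for (int i = 0; i < 2; ++i) {
      if (y[i] >= q.tap_threshold) {
        if (i == cue && !below) continue;  // require a fresh crossing of the cue
        latency = s * q.dt;
        selected = i;
        break;
      }
    }
    if (selected >= 0) break;
    if (y[cue] < q.tap_threshold) below = true;
  }
  NumericVector fin(13);
  for (int k = 0; k < 13; ++k) fin[k] = y[k];
  return List::create(_["latency_ms"] = latency,
                      _["selected"] = selected + 1,  // 1-based, 0 = timeout
                      _["state"] = fin);
}

// Alternate-tapping trial at constant dopaminergic input D.
// Protocol: settle `settle_ms` with no stimulus, then stimulate channel 1;
// a tap is registered when the cued channel's motor unit crosses
// tap_threshold (or at timeout); the stimulus stays on the tapped channel
// for `lag_ms` (movement execution), then switches to the other channel.
// [[Rcpp::export(name = ".bg_trial_cpp")]]
List bg_trial_cpp(NumericVector params, NumericVector wGo, NumericVector wNoGo,
                  double D, int n_cycles, double settle_ms) {
  BgParams q = unpack(params);
  double y[13] = {0};
  double st0[2] = {0, 0};
  const int nsettle = (int)std::round(settle_ms / q.dt);
  for (int s = 0; s < nsettle; ++s) euler_step(y, q, &wGo[0], &wNoGo[0], st0, D);

  NumericVector tap_times(n_cycles);
  IntegerVector timed_out(n_cycles);
  double t = 0.0;
  int cue = 0;
  for (int c = 0; c < n_cycles; ++c) {
    double st[2] = {0, 0};
    st[cue] = q.stim_amp;
    const int nstep = (int)std::round(q.timeout / q.dt);
    double lat = q.timeout;
    int to = 1;
    bool below = y[cue] < q.tap_threshold;
    for (int s = 1; s <= nstep; ++s) {
      euler_step(y, q, &wGo[0], &wNoGo[0], st, D);
      if (y[cue] < q.tap_threshold) below = true;
      else if (below) { lat = s * q.dt; to = 0; break; }
    }
    t += lat;
    tap_times[c] = t;
    timed_out[c] = to;
    // movement execution: stimulus held on tapped channel for the lag
    const int nlag = (int)std::round(q.lag / q.dt);
    for (int s = 0; s < nlag; ++s) euler_step(y, q, &wGo[0], &wNoGo[0], st, D);
    t += q.lag;
    cue = 1 - cue;
  }
  return List::create(_["tap_times_ms"] = tap_times,
                      _["timed_out"] = timed_out);
}
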