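pk:
  V1_l: 45.0
  V2_l: 90.0
  ka_per_min: 0.07
  initial_guess:
  - 1.5
  - 1.5
  - 3.0
pd:
  internal_grid_min: 1.0
  v3_l: 30.0
network:
  tau_ms: 10.0
  lag_ms: 90.0
  dt_ms: 0.1
  sig_a: 4.278516
  sig_u0: 1.0
  gGo: 0.424663
  gNoGo: 0.458935
  wL: 1.408468
  wThM: 0.589606
  wMTh: 4.488527
  wGoGPi: 0.827084
  wNoGoGPe: 1.675742
  wGPeGPi: 0.678754
  wGPiTh: 1.676767
  wChNoGo: 1.486496
  tonicGPe: 1.823292
  tonicGPi: 2.652605
  tonicCh: 1.449168
  alphaGo: 0.555659
  betaNoGo: 0.926979
  kChD: 0.776737
  stim_amp: 0.926288
  tap_threshold: 0.9
  timeout_ms: 2000.0
  wmax: 1.5
  w_init: 0.5
synth:
  n_stable: 13.0
  n_fluctuating: 13.0
  plasma_cv: 0.08
  tapping_sd: 7.0
estimation:
  n_restarts: 10.0
  k: 10.0
  ranges:
    ke3:
    - 0.005
    - 0.2
    T:
    - 0.0
    - 60.0
    Dmax:
    - 0.2
    - 5.0
    Dc50:
    - 0.1
    - 3.0
    ND:
    - 1.0
    - 15.0
stats:
  bonferroni_factor: 9.0
seed: 1.0
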