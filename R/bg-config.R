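# Network architecture and gains of the two-channel Go/NoGo model.
#
# Populations per action channel: motor cortex (M), Go and NoGo striatum
# (G, N), GPe (E), GPi/SNr (I), thalamus (Th); one shared tonically active
# cholinergic unit (Ch).  Every unit is a first-order low-pass filter with
# time constant `tau_ms` followed by the sigmoid
# 1 / (1 + exp(-a (u - u0))), so activities live in (0, 1).

#' Construct a basal-ganglia network configuration
#'
#' The default values are the package's calibrated configuration: they
#' satisfy the frequency-curve anchors (monotone curve; saturation at or
#' above 220 taps/min with `tau_ms = 10`, `lag_ms = 90`; approximately
#' 180 taps/min with the older `tau_ms = 15`, `lag_ms = 115` settings;
#' bradykinetic floor at D = 0 below 100 taps/min).  See
#' [calibrate_network()] to re-check or re-derive them.
#'
#' @param tau_ms Neuron time constant (ms).
#' @param lag_ms Inter-movement time lag between the two finger actions
#'   (ms).
#' @param dt_ms Euler integration step (ms); must satisfy
#'   `dt_ms <= tau_ms / 10`.
#' @param sig_a,sig_u0 Sigmoid slope and centre (shared by all
#'   populations).
#' @param gGo,gNoGo Cortico-striatal base gains; the effective drive of
#'   channel `i`'s Go (NoGo) unit is `gGo * wGo[i] * M[i]`
#'   (`gNoGo * wNoGo[i] * M[i]`), so the plastic [synapse_set()] weights
#'   scale these fixed gains.
#' @param wL Cortical lateral inhibition between the two channels.
#' @param wThM,wMTh Thalamus-to-motor-cortex and motor-cortex-to-thalamus
#'   gains (the positive feedback loop sustaining a selected action).
#' @param wGoGPi,wNoGoGPe,wGPeGPi,wGPiTh Gains of the direct and indirect
#'   pathway projections (all inhibitory).
#' @param wChNoGo Cholinergic excitation of the NoGo units.
#' @param tonicGPe,tonicGPi,tonicCh Tonic drives.
#' @param alphaGo Dopamine excitation of the winning Go unit (gated by
#'   the channel's relative cortical activity).
#' @param betaNoGo Dopamine inhibition of all NoGo units.
#' @param kChD Dopamine suppression of the cholinergic unit.
#' @param stim_amp External stimulus amplitude delivered to the cued
#'   channel.
#' @param tap_threshold Motor activity (fraction of unit saturation) at
#'   which a tap is registered.
#' @param timeout_ms Selection timeout: a cycle with no threshold crossing
#'   contributes this period.
#' @param wmax Upper bound for the plastic cortico-striatal weights.
#' @param w_init Naive (untrained) cortico-striatal weight.
#' @return An object of class `bg_config`.
#' @examples
#' cfg <- bg_config()
#' legacy <- bg_config(tau_ms = 15, lag_ms = 115)
#' @export
bg_config <- function(tau_ms = 10, lag_ms = 90, dt_ms = 0.1,
                      sig_a = 4.278516, sig_u0 = 1,
                      gGo = 0.424663, gNoGo = 0.458935,
                      wL = 1.408468, wThM = 0.589606, wMTh = 4.488527,
                      wGoGPi = 0.827084, wNoGoGPe = 1.675742,
                      wGPeGPi = 0.678754, wGPiTh = 1.676767,
                      wChNoGo = 1.486496,
                      tonicGPe = 1.823292, tonicGPi = 2.652605,
                      tonicCh = 1.449168,
                      alphaGo = 0.555659, betaNoGo = 0.926979,
                      kChD = 0.776737,
                      stim_amp = 0.926288, tap_threshold = 0.9,
                      timeout_ms = 2000, wmax = 1.5, w_init = 0.5) {
  cfg <- as.list(environment())
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      abort(paste0("configuration error: `", nm, "` must be a single finite number"),
            class = "levotap_config_error")
  }
  if (cfg$tau_ms <= 0 || cfg$dt_ms <= 0 || cfg$lag_ms <= 0)
    abort("configuration error: tau_ms, dt_ms and lag_ms must be positive",
          class = "levotap_config_error")
  if (cfg$dt_ms > cfg$tau_ms / 10)
    abort("configuration error: dt_ms must not exceed tau_ms / 10 (stability guard)",
          class = "levotap_config_error")
  if (cfg$tap_threshold <= 0 || cfg$tap_threshold >= 1)
    abort("configuration error: tap_threshold must lie in (0, 1)",
          class = "levotap_config_error")
  structure(cfg, class = "bg_config")
}

#' The calibrated default network configuration
#' @return A [bg_config()] with the shipped calibrated settings
#'   (`tau_ms = 10`, `lag_ms = 90`).
#' @export
default_bg_config <- function() bg_config()

#' The legacy network configuration
#'
#' Identical weights to the calibrated default but with the older neuron
#' time constant (15 ms) and inter-movement lag (115 ms), under which the
#' maximum tapping frequency is approximately 180 taps/min.
#' @return A [bg_config()].
#' @export
legacy_bg_config <- function() bg_config(tau_ms = 15, lag_ms = 115)

bg_param_vector <- function(cfg) {
  c(tau_ms = cfg$tau_ms, dt_ms = cfg$dt_ms, sig_a = cfg$sig_a,
    sig_u0 = cfg$sig_u0, gGo = cfg$gGo, gNoGo = cfg$gNoGo,
    wL = cfg$wL, wThM = cfg$wThM, wMTh = cfg$wMTh,
    wGoGPi = cfg$wGoGPi, wNoGoGPe = cfg$wNoGoGPe, wGPeGPi = cfg$wGPeGPi,
    wGPiTh = cfg$wGPiTh, wChNoGo = cfg$wChNoGo, tonicGPe = cfg$tonicGPe,
    tonicGPi = cfg$tonicGPi, tonicCh = cfg$tonicCh, alphaGo = cfg$alphaGo,
    betaNoGo = cfg$betaNoGo, kChD = cfg$kChD, stim_amp = cfg$stim_amp,
    tap_threshold = cfg$tap_threshold, timeout_ms = cfg$timeout_ms,
    lag_ms = cfg$lag_ms)
}

#' Plastic cortico-striatal weights
#'
#' Per-channel weights of the cortical projections onto the Go and NoGo
#' striatal units; the only synapses modified by Hebbian training.
#'
#' @param wGo,wNoGo Numeric length-2 vectors, one weight per action
#'   channel, in `[0, wmax]`.
#' @param wmax Upper clip bound.
#' @return An object of class `synapse_set`.
#' @export
synapse_set <- function(wGo = c(0.5, 0.5), wNoGo = c(0.5, 0.5), wmax = 1.5) {
  if (length(wGo) != 2 || length(wNoGo) != 2 ||
      anyNA(wGo) || anyNA(wNoGo) || any(!is.finite(c(wGo, wNoGo))))
    abort("input error: wGo and wNoGo must be finite length-2 vectors",
          class = "levotap_input_error")
  if (any(c(wGo, wNoGo) < 0) || any(c(wGo, wNoGo) > wmax))
    abort("input error: weights must lie in [0, wmax]",
          class = "levotap_input_error")
  structure(list(wGo = as.numeric(wGo), wNoGo = as.numeric(wNoGo),
                 wmax = wmax), class = "synapse_set")
}

#' @export
print.synapse_set <- function(x, ...) {
  cat(sprintf("<synapse_set> wGo = (%.3f, %.3f)  wNoGo = (%.3f, %.3f)\n",
              x$wGo[1], x$wGo[2], x$wNoGo[1], x$wNoGo[2]))
  invisible(x)
}

#' @export
print.bg_config <- function(x, ...) {
  cat(sprintf("<bg_config> tau = %g ms, lag = %g ms, dt = %g ms\n",
              x$tau_ms, x$lag_ms, x$dt_ms))
  cat("  gains:", paste(sprintf("%s=%.3g", setdiff(names(x),
      c("tau_ms", "lag_ms", "dt_ms")), unlist(x[setdiff(names(x),
      c("tau_ms", "lag_ms", "dt_ms"))])), collapse = " "), "\n")
  invisible(x)
}

state_names <- c("M1", "M2", "G1", "G2", "N1", "N2", "E1", "E2",
                 "I1", "I2", "Th1", "Th2", "Ch")

#' A resting network state
#'
#' @param config A [bg_config()].
#' @param synapses A [synapse_set()].
#' @param D Dopaminergic input held constant while settling.
#' @param settle_ms Relaxation time from zero activity (ms).
#' @return A named numeric vector of the 13 unit activities.
#' @export
bg_rest_state <- function(config = default_bg_config(),
                          synapses = default_synapses(), D = 0,
                          settle_ms = 400) {
  tr <- .bg_run_cpp(bg_param_vector(config), numeric(13),
                    synapses$wGo, synapses$wNoGo, c(0, 0), D, settle_ms, 0)
  stats::setNames(as.numeric(tr[nrow(tr), 2:14]), state_names)
}
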