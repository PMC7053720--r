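# Dopamine-gated Hebbian plasticity on the cortico-striatal synapses.
#
# A training epoch cues one of the two actions under heavy stimulus noise
# (so errors occur); immediately after the network's choice a phasic
# dopamine change is applied - a reward transiently doubles the current D,
# a punishment transiently nulls it - and the threshold Hebb rule
# gamma * pre * (post - theta) updates the Go synapses after rewards and
# the NoGo synapses after punishments.  The same rule produces both signs:
# with D nulled the NoGo units are highly active (post > theta), so
# punishments potentiate NoGo; with D doubled the Go units are active and
# rewards potentiate Go.

#' Threshold Hebb weight increment
#'
#' `dw = gamma * pre * (post - theta)`: potentiation when the
#' post-synaptic activity exceeds the threshold, depression below it.
#' The caller clips the resulting weight to `[0, wmax]`.
#'
#' @param pre,post Pre- and post-synaptic activities in `[0, 1]`
#'   (vectorised).
#' @param gamma Learning rate.
#' @param theta Post-synaptic threshold in (0, 1).
#' @return Weight increment(s).
#' @examples
#' hebbian_update(pre = 0.8, post = 0.9, gamma = 0.1, theta = 0.5)  # 0.032
#' @export
hebbian_update <- function(pre, post, gamma, theta) {
  stopifnot(all(pre >= 0 & pre <= 1), all(post >= 0 & post <= 1))
  gamma * pre * (post - theta)
}

#' Training protocol for a Hebbian session
#'
#' @param n_epochs Number of training epochs (cue presentations).
#' @param noise_sd Standard deviation of the Gaussian stimulus noise added
#'   to both channels; the default makes the action choice genuinely
#'   difficult (naive error rate roughly 30-50 percent).
#' @param reward_factor Phasic multiplier on the current dopaminergic
#'   input after a correct choice (reward = transient doubling).
#' @param punishment_factor Multiplier after an error (punishment =
#'   transient nulling).
#' @param phasic_duration_ms Duration of the phasic dopamine change
#'   (about one selection cycle).
#' @param gamma Hebbian learning rate.
#' @param theta Post-synaptic threshold.
#' @param session_time_min Minutes post-dose at which the session takes
#'   place (used by [simulate_training_experiment()]).
#' @param seed RNG seed for the session (`NULL` = use the current RNG
#'   stream).
#' @return An object of class `training_protocol`.
#' @export
training_protocol <- function(n_epochs = 50, noise_sd = 0.35,
                              reward_factor = 2, punishment_factor = 0,
                              phasic_duration_ms = 250,
                              gamma = 0.05, theta = 0.5,
                              session_time_min = 90, seed = NULL) {
  if (n_epochs < 1)
    abort("input error: n_epochs must be >= 1", class = "levotap_input_error")
  if (reward_factor < 0 || punishment_factor < 0 || gamma < 0)
    abort("input error: factors and gamma must be non-negative",
          class = "levotap_input_error")
  if (theta <= 0 || theta >= 1)
    abort("input error: theta must lie in (0, 1)", class = "levotap_input_error")
  structure(list(n_epochs = as.integer(n_epochs), noise_sd = noise_sd,
                 reward_factor = reward_factor,
                 punishment_factor = punishment_factor,
                 phasic_duration_ms = phasic_duration_ms,
                 gamma = gamma, theta = theta,
                 session_time_min = session_time_min, seed = seed),
            class = "training_protocol")
}

#' Run one Hebbian training session at a fixed dopaminergic input
#'
#' @param config A [bg_config()].
#' @param synapses Starting [synapse_set()].
#' @param protocol A [training_protocol()].
#' @param D Dopaminergic input at the moment of the session.
#' @return A list: `synapses` (updated weights) and `log`, a tibble with
#'   one row per epoch (cue, choice, outcome, latency and the weight
#'   trajectory).  Timeouts count as incorrect.
#' @export
run_training_session <- function(config, synapses, protocol, D) {
  stopifnot(inherits(config, "bg_config"), inherits(synapses, "synapse_set"),
            inherits(protocol, "training_protocol"))
  local_seed(protocol$seed, {
    p <- bg_param_vector(config)
    wGo <- synapses$wGo
    wNoGo <- synapses$wNoGo
    rest <- .bg_run_cpp(p, numeric(13), wGo, wNoGo, c(0, 0), D, 400, 0)
    rest <- as.numeric(rest[nrow(rest), 2:14])
    n <- protocol$n_epochs
    log <- vector("list", n)
    for (ep in seq_len(n)) {
      cue <- sample(1:2, 1)
      noise <- rnorm(2, 0, protocol$noise_sd)
      sel <- .bg_select_cpp(p, rest, wGo, wNoGo, cue - 1L, noise, D)
      choice <- sel$selected
      correct <- choice == cue
      fac <- if (correct) protocol$reward_factor else protocol$punishment_factor
      stim <- noise
      stim[cue] <- stim[cue] + config$stim_amp
      ph <- .bg_run_cpp(p, sel$state, wGo, wNoGo, stim, D * fac,
                        protocol$phasic_duration_ms, 0)
      s <- as.numeric(ph[nrow(ph), 2:14])
      M <- pmin(pmax(s[1:2], 0), 1)
      # the update targets the acted channel: the selected one, or the
      # cued (attempted) one when the selection timed out
      ch <- if (choice > 0) choice else cue
      if (correct) {
        dw <- hebbian_update(M[ch], min(max(s[2 + ch], 0), 1),
                             protocol$gamma, protocol$theta)
        wGo[ch] <- min(max(wGo[ch] + dw, 0), synapses$wmax)
      } else {
        dw <- hebbian_update(M[ch], min(max(s[4 + ch], 0), 1),
                             protocol$gamma, protocol$theta)
        wNoGo[ch] <- min(max(wNoGo[ch] + dw, 0), synapses$wmax)
      }
      log[[ep]] <- tibble::tibble(epoch = ep, cue = cue, choice = choice,
                                  outcome = ifelse(correct, "reward",
                                                   "punishment"),
                                  latency_ms = sel$latency_ms,
                                  wGo1 = wGo[1], wGo2 = wGo[2],
                                  wNoGo1 = wNoGo[1], wNoGo2 = wNoGo[2])
    }
    list(synapses = synapse_set(wGo, wNoGo, synapses$wmax),
         log = dplyr::bind_rows(log))
  })
}

#' Cortico-striatal synapse presets by training level
#'
#' Deterministically trains a naive synapse set (both weights at
#' `config$w_init`) for the requested number of epochs under a fixed
#' standard protocol (moderate dopaminergic tone, heavy stimulus noise)
#' and a fixed seed.  Level 100 is the package's "moderate-skill PD"
#' default; 60 and 80 represent poor skill, 150 and 200 high skill.
#'
#' @param level One of 60, 80, 100, 150, 200 (training epochs).
#' @param config A [bg_config()].
#' @param seed Seed of the standard training run.
#' @return A [synapse_set()].
#' @export
synapse_presets <- function(level, config = default_bg_config(),
                            seed = 20200303) {
  if (!length(level) == 1 || !level %in% c(60, 80, 100, 150, 200))
    abort("input error: level must be one of 60, 80, 100, 150, 200",
          class = "levotap_input_error")
  key <- rlang::hash(list(unclass(config), level, seed))
  if (!is.null(the$preset_cache[[key]])) return(the$preset_cache[[key]])
  proto <- training_protocol(n_epochs = level, seed = seed)
  naive <- synapse_set(rep(config$w_init, 2), rep(config$w_init, 2),
                       config$wmax)
  res <- run_training_session(config, naive, proto, D = preset_training_D)
  if (is.null(the$preset_cache)) the$preset_cache <- list()
  the$preset_cache[[key]] <- res$synapses
  res$synapses
}

# dopaminergic tone of the standard preset-generating sessions: a
# moderately medicated state on the rising part of the frequency curve
preset_training_D <- 1.5

#' The default "moderate-skill PD" synapse set (100-epoch preset)
#' @param config A [bg_config()].
#' @return A [synapse_set()].
#' @export
default_synapses <- function(config = default_bg_config()) {
  synapse_presets(100, config)
}

#' Simulate a training experiment on a fitted patient
#'
#' Computes the dopaminergic input at the session time from the patient's
#' fitted PK/PD parameters, runs a Hebbian training session at that `D`,
#' recomputes the frequency curve with the trained synapses, and returns
#' the untrained and post-training tapping trajectories side by side.
#' Training early after dosing (high D, effective rewards) tends to leave
#' the trajectory intact or mildly improved; training hours after dosing
#' in a fluctuating patient (D back near zero, strong punishments) builds
#' up NoGo weights and can push the tapping rate below the pre-dose
#' baseline - the model's aberrant-learning regime.
#'
#' @param pk,pd Fitted [pk_parameters()] and [pd_parameters()].
#' @param protocol A [training_protocol()]; `session_time_min` selects
#'   the training moment (e.g. 90 or 210 min post-dose).
#' @param config A [bg_config()].
#' @param synapses Pre-training [synapse_set()].
#' @param dose A [dose_event()].
#' @param times Evaluation times (min) of the returned trajectories.
#' @return A tibble of class `training_experiment` with columns
#'   `time_min`, `untrained`, `trained`; attributes `session`
#'   (the session log), `synapses_trained`, `D_session` and
#'   `baseline` (pre-dose tapping rate).
#' @export
simulate_training_experiment <- function(pk, pd, protocol = training_protocol(),
                                         config = default_bg_config(),
                                         synapses = default_synapses(config),
                                         dose = dose_event(),
                                         times = seq(0, 240, by = 5)) {
  stopifnot(inherits(pk, "pk_parameters"), inherits(pd, "pd_parameters"))
  Dser <- dopaminergic_series(pk, pd, dose, times)
  curve0 <- steady_state_frequency_curve(config, synapses)
  untrained <- curve_interp(curve0, Dser$D)
  D_sess <- dopaminergic_series(pk, pd, dose, protocol$session_time_min)$D
  sess <- run_training_session(config, synapses, protocol, D_sess)
  curve1 <- steady_state_frequency_curve(config, sess$synapses)
  trained <- curve_interp(curve1, Dser$D)
  out <- tibble::tibble(time_min = times, untrained = untrained,
                        trained = trained)
  class(out) <- c("training_experiment", class(out))
  attr(out, "session") <- sess$log
  attr(out, "synapses_trained") <- sess$synapses
  attr(out, "D_session") <- D_sess
  attr(out, "baseline") <- curve_interp(curve0, pd$D0)
  attr(out, "session_time_min") <- protocol$session_time_min
  out
}
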