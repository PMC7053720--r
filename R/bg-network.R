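# Simulation of alternate finger tapping by the Go/NoGo network, and the
# quasi-static bridge between the minute-scale dopaminergic input and the
# millisecond-scale network: because the network settles within tens of
# milliseconds while D(t) evolves over minutes, tapping frequency at any
# instant is read off the steady-state frequency-vs-D curve.

#' Advance the network state by one Euler step
#'
#' @param state Named 13-vector of activities (see [bg_rest_state()]).
#' @param config A [bg_config()].
#' @param synapses A [synapse_set()].
#' @param stimulus Length-2 external drive to the two motor-cortex
#'   channels.
#' @param D Dopaminergic input (dimensionless).
#' @param dt Step size (ms); defaults to `config$dt_ms`.
#' @return The updated named state vector.
#' @export
step_network <- function(state, config, synapses, stimulus = c(0, 0),
                         D = 0, dt = config$dt_ms) {
  if (dt > config$tau_ms / 10)
    abort("configuration error: dt must not exceed tau/10",
          class = "levotap_config_error")
  p <- bg_param_vector(config)
  p["dt_ms"] <- dt
  tr <- .bg_run_cpp(p, as.numeric(state), synapses$wGo, synapses$wNoGo,
                    as.numeric(stimulus), D, dt, 0)
  stats::setNames(as.numeric(tr[nrow(tr), 2:14]), state_names)
}

#' Run the network for a fixed duration and record the trajectory
#'
#' @inheritParams step_network
#' @param duration_ms Simulated time (ms).
#' @param record_every_ms Sampling interval of the returned trajectory.
#' @return A tibble: `time_ms` plus one column per unit.
#' @export
run_network <- function(state, config, synapses, stimulus = c(0, 0), D = 0,
                        duration_ms = 500, record_every_ms = 1) {
  tr <- .bg_run_cpp(bg_param_vector(config), as.numeric(state),
                    synapses$wGo, synapses$wNoGo, as.numeric(stimulus), D,
                    duration_ms, record_every_ms)
  colnames(tr) <- c("time_ms", state_names)
  tibble::as_tibble(as.data.frame(tr))
}

#' Simulate one alternate-tapping trial at constant dopaminergic input
#'
#' The stimulus is presented to channel 1; a tap is registered when the
#' cued channel's motor unit crosses `tap_threshold` (or, failing that,
#' at `timeout_ms`); the stimulus stays on the tapped channel for the
#' inter-movement lag (movement execution) and then switches to the other
#' channel.  The reported frequency is `60000 / mean inter-tap interval`,
#' discarding the first two cycles (transient).  The dynamics are
#' deterministic.
#'
#' @param config A [bg_config()].
#' @param synapses A [synapse_set()].
#' @param D Constant dopaminergic input.
#' @param n_cycles Number of tap cycles to simulate (>= 3).
#' @param duration_ms Optional cap on simulated time; cycles beyond it are
#'   dropped.
#' @param settle_ms Relaxation time before the first stimulus.
#' @return A list of class `tapping_trial`: `tap_times_ms`, `timed_out`
#'   flags and `taps_per_min`.
#' @examples
#' trial <- simulate_tapping_trial(default_bg_config(), synapse_set(), D = 2)
#' trial$taps_per_min
#' @export
simulate_tapping_trial <- function(config = default_bg_config(),
                                   synapses = default_synapses(),
                                   D = 0, n_cycles = 20,
                                   duration_ms = NULL, settle_ms = 400) {
  stopifnot(inherits(config, "bg_config"), inherits(synapses, "synapse_set"))
  if (!is.null(duration_ms))
    n_cycles <- max(n_cycles,
                    ceiling(duration_ms / (config$lag_ms + 4 * config$tau_ms)))
  if (n_cycles < 3)
    abort("input error: need at least 3 cycles", class = "levotap_input_error")
  tr <- .bg_trial_cpp(bg_param_vector(config), synapses$wGo, synapses$wNoGo,
                      D, as.integer(n_cycles), settle_ms)
  tap <- tr$tap_times_ms
  keep <- if (is.null(duration_ms)) seq_along(tap) else which(tap <= duration_ms)
  if (length(keep) >= 3) tap <- tap[keep]
  iti <- diff(tap[-(1:2)])
  freq <- if (length(iti) >= 1) 60000 / mean(iti)
          else 60000 / (config$timeout_ms + config$lag_ms)
  structure(list(tap_times_ms = tap, timed_out = tr$timed_out[seq_along(tap)],
                 taps_per_min = freq, D = D),
            class = "tapping_trial")
}

#' @export
print.tapping_trial <- function(x, ...) {
  cat(sprintf("<tapping_trial> D = %.3g: %d taps, %.1f taps/min (%d timeouts)\n",
              x$D, length(x$tap_times_ms), x$taps_per_min, sum(x$timed_out)))
  invisible(x)
}

#' Steady-state tapping frequency as a function of dopaminergic input
#'
#' Evaluates [simulate_tapping_trial()] on an ascending grid of `D`
#' values.  After calibration the curve is sigmoid-like and monotone
#' non-decreasing; a non-monotone result raises a calibration-violation
#' warning.  Results are cached per (config, synapses, grid) so repeated
#' calls inside the estimator are free.
#'
#' @inheritParams simulate_tapping_trial
#' @param D_grid Ascending grid of dopaminergic-input values (>= 20
#'   points recommended, spanning 0 to saturation).
#' @return A tibble of class `frequency_curve` with columns `D` and
#'   `taps_per_min`.
#' @examples
#' curve <- steady_state_frequency_curve(D_grid = seq(0, 5, by = 0.5))
#' @export
steady_state_frequency_curve <- function(config = default_bg_config(),
                                         synapses = default_synapses(),
                                         D_grid = seq(0, 5, by = 0.2),
                                         n_cycles = 20) {
  stopifnot(inherits(config, "bg_config"), inherits(synapses, "synapse_set"))
  if (any(diff(D_grid) <= 0) || any(D_grid < 0))
    abort("input error: D_grid must be non-negative and ascending",
          class = "levotap_input_error")
  key <- rlang::hash(list(unclass(config), synapses$wGo, synapses$wNoGo,
                          D_grid, n_cycles))
  if (!is.null(the$curve_cache[[key]])) return(the$curve_cache[[key]])
  f <- vapply(D_grid, function(D)
    simulate_tapping_trial(config, synapses, D, n_cycles)$taps_per_min,
    numeric(1))
  out <- tibble::tibble(D = D_grid, taps_per_min = f)
  class(out) <- c("frequency_curve", class(out))
  if (any(diff(f) < -1e-6))
    warn("calibration violation: frequency curve is not monotone non-decreasing",
         class = "levotap_calibration_warning")
  if (is.null(the$curve_cache)) the$curve_cache <- list()
  the$curve_cache[[key]] <- out
  out
}

#' Tapping-frequency series from a dopaminergic-input series
#'
#' Quasi-static bridge: each `D(t)` value is converted to a frequency by
#' linear interpolation of the steady-state curve; values outside the
#' grid are clamped to the curve ends.
#'
#' @param curve A `frequency_curve` from
#'   [steady_state_frequency_curve()].
#' @param D_series A tibble with `time_min` and `D`.
#' @return A tibble with `time_min` and `taps_per_min`.
#' @export
frequency_from_D_series <- function(curve, D_series) {
  check_series(D_series)
  tibble::tibble(time_min = series_times(D_series),
                 taps_per_min = curve_interp(curve, series_values(D_series)))
}

curve_interp <- function(curve, D) {
  approx(curve$D, curve$taps_per_min,
         xout = pmin(pmax(D, min(curve$D)), max(curve$D)), rule = 2,
         ties = "ordered")$y
}

#' Invert the frequency curve
#'
#' Returns the smallest dopaminergic input at which the (monotone) curve
#' reaches a target frequency, clamped to the grid ends outside the
#' curve's range.  Used to initialise `D0` from a patient's pre-dose
#' tapping rate.
#'
#' @param curve A `frequency_curve`.
#' @param f Target frequency (taps/min).
#' @return A dopaminergic-input value.
#' @export
invert_frequency <- function(curve, f) {
  y <- curve$taps_per_min
  if (f <= y[1]) return(curve$D[1])
  if (f >= max(y)) return(curve$D[which.max(y >= max(y))])
  i <- which(y >= f)[1]  # first grid point at or above the target
  x0 <- curve$D[i - 1]; x1 <- curve$D[i]
  y0 <- y[i - 1]; y1 <- y[i]
  if (y1 == y0) return(x1)
  x0 + (f - y0) / (y1 - y0) * (x1 - x0)
}

#' Calibration constraints for the frequency curve
#'
#' The four anchors the shipped configuration satisfies: (1) monotone
#' curve on the `D` grid; (2) saturation frequency at least
#' `max_default` with the default time constant and lag; (3) saturation
#' frequency within `legacy_tol` of `max_legacy` when `tau_ms = 15`,
#' `lag_ms = 115`; (4) frequency at `D = 0` at most `floor_max`.
#'
#' @param max_default,max_legacy,legacy_tol,floor_max Numeric anchors.
#' @return A list of constraint descriptors.
#' @export
bg_calibration_constraints <- function(max_default = 220, max_legacy = 180,
                                       legacy_tol = 0.1, floor_max = 100) {
  list(monotone = list(),
       max_default = list(value = max_default),
       max_legacy = list(value = max_legacy, tol = legacy_tol),
       floor = list(value = floor_max))
}

check_calibration <- function(config, synapses, constraints,
                              D_grid = seq(0, 5, by = 0.25)) {
  curve <- steady_state_frequency_curve(config, synapses, D_grid)
  legacy <- NULL
  rows <- list()
  for (nm in names(constraints)) {
    cs <- constraints[[nm]]
    row <- switch(nm,
      monotone = {
        v <- min(diff(curve$taps_per_min))
        tibble::tibble(constraint = nm, value = v, ok = v >= -1e-6)
      },
      max_default = {
        v <- max(curve$taps_per_min)
        tibble::tibble(constraint = nm, value = v, ok = v >= cs$value)
      },
      max_legacy = {
        lc <- config
        lc$tau_ms <- 15; lc$lag_ms <- 115
        legacy <- steady_state_frequency_curve(lc, synapses, D_grid)
        v <- max(legacy$taps_per_min)
        tibble::tibble(constraint = nm, value = v,
                       ok = abs(v - cs$value) <= cs$tol * cs$value)
      },
      floor = {
        v <- curve$taps_per_min[1]
        tibble::tibble(constraint = nm, value = v, ok = v <= cs$value)
      },
      abort(paste0("unknown constraint: ", nm), class = "levotap_input_error"))
    rows[[nm]] <- row
  }
  dplyr::bind_rows(rows)
}

#' Check or re-derive a network configuration against the curve anchors
#'
#' If `config` already satisfies every constraint it is returned
#' unchanged (with the check table attached as attribute `"checks"`).
#' Otherwise a coordinate search over the dopamine gains and tonic drives
#' (multiplicative perturbations) looks for a satisfying configuration;
#' if the search budget is exhausted a calibration-failure error carrying
#' the best-found report is raised.  An empty constraint list returns the
#' input configuration unchanged.
#'
#' @param config Starting [bg_config()].
#' @param synapses A [synapse_set()].
#' @param constraints As produced by [bg_calibration_constraints()].
#' @param search_fields Configuration fields the search may scale.
#' @param steps Multiplicative perturbation factors explored per field.
#' @param max_rounds Coordinate-search rounds.
#' @return A [bg_config()] satisfying the constraints.
#' @export
calibrate_network <- function(config = default_bg_config(),
                              synapses = default_synapses(),
                              constraints = bg_calibration_constraints(),
                              search_fields = c("alphaGo", "betaNoGo",
                                                "tonicGPi", "stim_amp"),
                              steps = c(0.9, 0.95, 1.05, 1.1),
                              max_rounds = 3) {
  if (length(constraints) == 0) return(config)
  score <- function(cfg) {
    ck <- check_calibration(cfg, synapses, constraints)
    list(checks = ck, n_bad = sum(!ck$ok))
  }
  cur <- score(config)
  if (cur$n_bad == 0) {
    attr(config, "checks") <- cur$checks
    return(config)
  }
  best <- config; best_s <- cur
  for (round in seq_len(max_rounds)) {
    improved <- FALSE
    for (fld in search_fields) {
      for (st in steps) {
        cand <- best
        cand[[fld]] <- best[[fld]] * st
        s <- score(cand)
        if (s$n_bad < best_s$n_bad) {
          best <- cand; best_s <- s; improved <- TRUE
        }
        if (best_s$n_bad == 0) break
      }
      if (best_s$n_bad == 0) break
    }
    if (best_s$n_bad == 0 || !improved) break
  }
  if (best_s$n_bad > 0)
    abort(paste0("calibration failure: ", best_s$n_bad,
                 " constraint(s) unmet; best-found report attached"),
          class = "levotap_calibration_failure",
          checks = best_s$checks, best = best)
  attr(best, "checks") <- best_s$checks
  best
}
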