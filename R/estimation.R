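# Two-stage automatic parameter estimation.  Stage 1 ([fit_pk()]) mimics
# the plasma concentration; stage 2 (here) fits the six pharmacodynamic
# parameters by multi-restart Nelder-Mead minimisation of a cost that
# combines the sum of squared tapping errors with the weighted maximum
# absolute error:
#
#   F(theta) = sum_i (fmod(t_i) - fmeas(t_i))^2 + k * max_i |fmod - fmeas|
#
# with k = 10.  The max-error term penalises missing the rapid end-of-dose
# fall of fluctuating patients.  fmod is evaluated quasi-statically via
# the precomputed steady-state frequency curve.

#' Pharmacodynamic cost function
#'
#' @param pd A [pd_parameters()] candidate.
#' @param patient A patient record (see [generate_patient()] or
#'   [read_patient_csv()]); its tapping series supplies the measurement
#'   instants and values.
#' @param pk Fixed plasma kinetic parameters (from [fit_pk()]).
#' @param curve A `frequency_curve`.
#' @param k Weight of the maximum-absolute-error term.
#' @param dose A [dose_event()].
#' @return The scalar cost (>= 0).
#' @export
pd_cost <- function(pd, patient, pk, curve, k = 10, dose = dose_event()) {
  stopifnot(inherits(pd, "pd_parameters"))
  if (inherits(pk, "pk_fit")) pk <- pk$parameters
  tap <- patient$tapping
  check_series(tap)
  fmod <- curve_interp(curve,
                       dopaminergic_series(pk, pd, dose, series_times(tap))$D)
  res <- fmod - series_values(tap)
  sum(res^2) + k * max(abs(res))
}

# fast closure over the patient: precomputes the dense plasma solution
# so each candidate evaluation only runs the effect/delay/Hill stages
make_pd_objective <- function(patient, pk, curve, k = 10,
                              dose = dose_event(), grid_min = 1) {
  tap <- patient$tapping
  tt <- series_times(tap)
  ff <- series_values(tap)
  tg <- seq(0, ceiling((max(tt) + 60) / grid_min) * grid_min, by = grid_min)
  terms <- pk_exp_terms(pk, dose)
  c1 <- if (is.null(terms)) simulate_plasma(pk, dose, tg)$conc_mg_l
        else eval_exp_terms(terms, tg)
  cd <- curve$D
  cf <- curve$taps_per_min
  function(th) {
    # th = c(ke3, T, D0, Dmax, Dc50, ND), natural scale
    .pd_cost_cpp(th, c1, grid_min, tt, ff, cd, cf, k)
  }
}

softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))
softplus_inv <- function(x) ifelse(x > 30, x, log(expm1(pmax(x, 1e-9))))

# transformed optimisation coordinates: positivity by log/softplus, and the
# Hill pair expressed as (u, ND) with u = ND log(Dc50), which straightens
# the Dc50/ND compensation valley of the cost surface
pd_from_z <- function(z) {
  ND <- exp(z[6])
  c(exp(z[1]), softplus(z[2]), exp(z[3]), exp(z[4]), exp(z[5] / ND), ND)
}
pd_to_z <- function(th) {
  c(log(th[1]), softplus_inv(th[2]), log(th[3]), log(th[4]),
    th[6] * log(th[5]), log(th[6]))
}

#' Fit the six pharmacodynamic parameters of one patient
#'
#' Multi-restart derivative-free estimation: for each restart, `ke3`,
#' `Dmax`, `Dc50` and `ND` are drawn log-uniformly and `T` uniformly from
#' the configured ranges, while the initial `D0` is computed (by
#' inverting the frequency curve) so that the model starts at the
#' patient's pre-dose tapping rate; all six parameters are then free
#' during the simplex minimisation, and the deepest minimum across
#' restarts is returned (followed by extra polishing rounds).  Each
#' restart iterates the simplex (a fresh simplex started from the previous
#' optimum) until the cost stops improving.  Positivity is enforced by
#' log-transforms (`T` via a softplus map) and the Hill pair is optimised
#' as `(ND log Dc50, log ND)`, which conditions the search space.
#'
#' @param patient A patient record with a `tapping` series containing a
#'   pre-dose (t = 0) sample.
#' @param pk_fit A `pk_fit` or [pk_parameters()].
#' @param curve A `frequency_curve`; defaults to the curve of the default
#'   configuration and synapses.
#' @param n_restarts Number of random restarts.
#' @param seed RNG seed for the restart draws.
#' @param k Cost-function weight of the maximum-error term.
#' @param ranges Restart sampling ranges.
#' @param dose A [dose_event()].
#' @param maxit Simplex iteration budget per restart.
#' @param prior_lambda Weight of the weak log-normal shrinkage prior that
#'   regularises the flat directions of the cost surface (0 disables it);
#'   the reported cost is always the pure unpenalised objective.
#' @return An object of class `pd_fit`: best [pd_parameters()], `cost`,
#'   `r2` (tapping), per-restart diagnostics, `best_restart`, `seed` and
#'   a `converged` flag per restart.  If no restart converges the result
#'   is flagged, not an error.
#' @export
fit_pd <- function(patient, pk_fit, curve = NULL, n_restarts = 10, seed = 1,
                   k = 10,
                   ranges = list(ke3 = c(0.005, 0.2), T = c(0, 60),
                                 Dmax = c(0.2, 5), Dc50 = c(0.1, 3),
                                 ND = c(1, 15)),
                   dose = dose_event(), maxit = 2000, prior_lambda = 2) {
  pk <- if (inherits(pk_fit, "pk_fit")) pk_fit$parameters else pk_fit
  if (is.null(curve)) curve <- steady_state_frequency_curve()
  tap <- patient$tapping
  check_series(tap)
  tt <- series_times(tap)
  base_idx <- which(tt == 0)
  if (length(base_idx) == 0) {
    warn("no pre-dose tapping sample; using the earliest sample as baseline")
    base_idx <- 1
  }
  f0 <- series_values(tap)[base_idx[1]]
  D0_init <- invert_frequency(curve, f0)
  # dense plasma solution shared by every cost evaluation
  grid_min <- 0.5
  tg <- seq(0, ceiling((max(tt) + 60) / grid_min) * grid_min, by = grid_min)
  terms <- pk_exp_terms(pk, dose)
  c1 <- if (is.null(terms)) simulate_plasma(pk, dose, tg)$conc_mg_l
        else eval_exp_terms(terms, tg)
  # soft box: the search is confined to the configured physiological
  # ranges (with a half-decade of slack) by a quadratic penalty, so noisy
  # data cannot push the fit into degenerate corners (ke3 -> plasma
  # tracking, ND -> step response) that carry no physiological meaning
  lo <- c(ranges$ke3[1] / 2, ranges$T[1], 0.01, ranges$Dmax[1] / 2,
          ranges$Dc50[1] / 2, ranges$ND[1] / 1.5)
  hi <- c(ranges$ke3[2] * 2, ranges$T[2] * 1.5, 5, ranges$Dmax[2] * 2,
          ranges$Dc50[2] * 2, ranges$ND[2] * 1.5)
  # weak MAP prior: log-space shrinkage to the geometric centre of each
  # configured range (arithmetic centre for T); it resolves the flat
  # directions of the cost surface (the Emax Dmax/Dc50 trade-off and the
  # step-response ND limit) without noticeably biasing well-identified
  # parameters
  prior_c <- c(mean(log(ranges$ke3)), mean(ranges$T), 0,
               mean(log(ranges$Dmax)), mean(log(ranges$Dc50)),
               mean(log(ranges$ND)))
  prior_w <- c(diff(log(ranges$ke3)) / 2, diff(ranges$T) / 2, 0,
               diff(log(ranges$Dmax)) / 2, diff(log(ranges$Dc50)) / 2,
               diff(log(ranges$ND)) / 2)
  restart_nm <- function(z0, rounds = 3)
    .pd_fit_restart_cpp(z0, c1, grid_min, tt, series_values(tap),
                        curve$D, curve$taps_per_min, k, lo, hi,
                        prior_c, prior_w, prior_lambda,
                        as.integer(maxit), 1e-10, as.integer(rounds))
  draws <- local_seed(seed, lapply(seq_len(n_restarts), function(i) {
    c(ke3 = exp(runif(1, log(ranges$ke3[1]), log(ranges$ke3[2]))),
      T = runif(1, ranges$T[1], ranges$T[2]),
      D0 = max(D0_init, 1e-3),
      Dmax = exp(runif(1, log(ranges$Dmax[1]), log(ranges$Dmax[2]))),
      Dc50 = exp(runif(1, log(ranges$Dc50[1]), log(ranges$Dc50[2]))),
      ND = exp(runif(1, log(ranges$ND[1]), log(ranges$ND[2]))))
  }))
  restarts <- vector("list", n_restarts)
  for (i in seq_len(n_restarts)) {
    init <- draws[[i]]
    opt <- restart_nm(pd_to_z(init))
    restarts[[i]] <- tibble::tibble(
      restart = i, cost = opt$value, converged = is.finite(opt$value),
      evals = opt$evals,
      init_ke3 = init[["ke3"]], init_T = init[["T"]], init_D0 = init[["D0"]],
      init_Dmax = init[["Dmax"]], init_Dc50 = init[["Dc50"]],
      init_ND = init[["ND"]], par = list(opt$z))
  }
  rtab <- dplyr::bind_rows(restarts)
  best <- which.min(rtab$cost)
  # polish the deepest minimum with further simplex rounds; the restart
  # table keeps the raw per-restart outcomes
  pol <- restart_nm(rtab$par[[best]], rounds = 4)
  zbest <- if (pol$value < rtab$cost[best]) pol$z else rtab$par[[best]]
  th <- pd_from_z(zbest)
  pure_cost <- .pd_cost_cpp(th, c1, grid_min, tt, series_values(tap),
                            curve$D, curve$taps_per_min, k)
  pd <- pd_parameters(ke3 = th[1], T = th[2], D0 = th[3], Dmax = th[4],
                      Dc50 = th[5], ND = th[6])
  fmod <- curve_interp(curve, dopaminergic_series(pk, pd, dose, tt)$D)
  r2 <- compute_r2(fmod, series_values(tap))
  structure(list(parameters = pd, cost = pure_cost, r2 = r2,
                 n_restarts = n_restarts, best_restart = best,
                 seed = seed, converged = any(rtab$converged),
                 restarts = dplyr::select(rtab, -"par"),
                 curve = curve, pk = pk, dose = dose),
            class = "pd_fit")
}

#' @export
print.pd_fit <- function(x, ...) {
  cat(sprintf("<pd_fit>  cost = %.4g  R2 = %.4f  best restart %d/%d%s\n",
              x$cost, x$r2, x$best_restart, x$n_restarts,
              if (!x$converged) " [no restart converged]" else ""))
  print(x$parameters)
  invisible(x)
}

#' Coefficient of determination
#'
#' `R2 = 1 - SSres / SStot`, with the total sum of squares taken about
#' the observed mean.  Values above 0.8 are conventionally read as a good
#' fit of the tapping series.
#'
#' @param predicted,observed Numeric vectors on the same grid (or series
#'   tibbles), length >= 2; `observed` must not be constant.
#' @return A scalar (at most 1).
#' @export
compute_r2 <- function(predicted, observed) {
  if (is.data.frame(predicted)) predicted <- series_values(predicted)
  if (is.data.frame(observed)) observed <- series_values(observed)
  if (length(predicted) != length(observed))
    abort("input error: predicted and observed must have equal length",
          class = "levotap_input_error")
  if (length(observed) < 2)
    abort("input error: need at least 2 points", class = "levotap_input_error")
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0)
    abort("undefined R2: observed series is constant",
          class = "levotap_degenerate_data")
  1 - sum((predicted - observed)^2) / sstot
}

#' Robustness of a fitted trajectory to the assumed synapse level
#'
#' For each cortico-striatal preset (training level), the basal
#' dopaminergic input `D0` is re-derived so the model reproduces the same
#' pre-dose tapping rate, the other five pharmacodynamic parameters are
#' held at their estimates, and the post-dose trajectory is regenerated.
#' Reported per level: the adjusted `D0`, the sup-norm deviation from the
#' reference (level-100) trajectory, and the stable/fluctuating
#' classification of the regenerated trajectory.
#'
#' @param pk,pd Fitted parameters of the patient.
#' @param levels Preset levels to examine.
#' @param config A [bg_config()].
#' @param dose A [dose_event()].
#' @param times Trajectory evaluation grid (min).
#' @return A tibble with columns `level`, `D0`, `sup_dev`,
#'   `sup_dev_rel` and `classification`.
#' @export
synapse_sensitivity_analysis <- function(pk, pd,
                                         levels = c(60, 80, 100, 150, 200),
                                         config = default_bg_config(),
                                         dose = dose_event(),
                                         times = seq(0, 240, by = 5)) {
  stopifnot(inherits(pk, "pk_parameters"), inherits(pd, "pd_parameters"))
  ref_curve <- steady_state_frequency_curve(config, synapse_presets(100, config))
  f_base <- curve_interp(ref_curve, pd$D0)
  traj_for <- function(level) {
    curve <- steady_state_frequency_curve(config, synapse_presets(level, config))
    D0 <- invert_frequency(curve, f_base)
    pd_l <- pd_parameters(ke3 = pd$ke3, T = pd$T, D0 = D0, Dmax = pd$Dmax,
                          Dc50 = pd$Dc50, ND = pd$ND)
    f <- curve_interp(curve, dopaminergic_series(pk, pd_l, dose, times)$D)
    list(D0 = D0, f = f)
  }
  ref <- traj_for(100)
  purrr::map_dfr(levels, function(lv) {
    tr <- traj_for(lv)
    tap <- tibble::tibble(time_min = times, taps_per_min = tr$f)
    cls <- suppressWarnings(classify_response(tap, baseline = tr$f[1]))
    tibble::tibble(level = lv, D0 = tr$D0,
                   sup_dev = max(abs(tr$f - ref$f)),
                   sup_dev_rel = max(abs(tr$f - ref$f)) / max(abs(ref$f)),
                   classification = as.character(cls))
  })
}
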