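# Effect-site dynamics and the Hill concentration-effect law.
#
# The effect compartment follows the classical link model
#   c3' = ke3 (c1(t) - c3),   c3(0) = 0  (12-hour washout),
# which has unit steady-state gain; any true input gain is absorbed into
# the fitted Dc50.  On a uniform grid with c1 piecewise linear the update
#   c3[n+1] = c1[n+1] - s/ke3 + (c3[n] - c1[n] + s/ke3) exp(-ke3 h)
# (s the local slope of c1) is exact, so no additional integration error
# is introduced beyond the linear interpolation of c1.

effect_step <- function(c1, ke3, h, c3_0 = 0) {
  n <- length(c1)
  if (n == 1) return(c3_0)
  s <- diff(c1) / h
  al <- exp(-ke3 * h)
  beta <- c1[-1] - s / ke3 - (c1[-n] - s / ke3) * al
  as.numeric(stats::filter(beta, al, method = "recursive", init = c3_0))
}

#' Effect-site concentration from plasma concentration
#'
#' Solves the link-compartment equation `c3' = ke3 (c1 - c3)` with
#' `c3(0) = 0`, densely on an internal uniform grid (default 1 min) with
#' an exact exponential update, and returns `c3` on the input time grid.
#'
#' @param conc A tibble with `time_min` and the plasma concentration
#'   (mg/l) in the second column.
#' @param ke3 Effect-compartment removal rate (1/min), > 0.
#' @param grid_min Internal integration grid step (min).
#' @param dense If `TRUE`, return the dense internal grid instead of the
#'   input grid (used by the delay stage).
#' @return A tibble with columns `time_min` and `c3_mg_l`.
#' @export
effect_compartment <- function(conc, ke3, grid_min = 1, dense = FALSE) {
  check_series(conc)
  if (!is.numeric(ke3) || length(ke3) != 1 || !is.finite(ke3) || ke3 <= 0)
    abort("invalid-parameter: `ke3` must be a single positive number",
          class = "levotap_invalid_parameter")
  tt <- series_times(conc)
  cc <- series_values(conc)
  tg <- seq(tt[1], tt[length(tt)], by = grid_min)
  cg <- approx(tt, cc, xout = tg, rule = 2)$y
  c3g <- c(0, effect_step(cg, ke3, grid_min))[seq_along(tg)]
  if (length(tg) == 1) c3g <- 0
  if (dense) return(tibble::tibble(time_min = tg, c3_mg_l = c3g))
  tibble::tibble(time_min = tt,
                 c3_mg_l = approx(tg, c3g, xout = tt, rule = 2)$y)
}

#' Apply the pure motor-effect delay
#'
#' `c3delay(t) = c3(t - T)`; before the delay has elapsed the effect-site
#' concentration is the pre-dose value 0 (the baseline dopaminergic tone
#' lives entirely in `D0`).  Off-grid delayed values are linearly
#' interpolated.
#'
#' @param series A tibble with `time_min` and a value column.
#' @param T Pure delay (min), >= 0.
#' @return A tibble on the same time grid, value column named as input.
#' @export
apply_delay <- function(series, T) {
  check_series(series)
  if (!is.numeric(T) || length(T) != 1 || !is.finite(T) || T < 0)
    abort("invalid-parameter: `T` must be a single non-negative number",
          class = "levotap_invalid_parameter")
  tt <- series_times(series)
  vv <- series_values(series)
  if (T == 0) return(series)
  shifted <- approx(tt, vv, xout = tt - T, rule = 1)$y
  shifted[tt - T < tt[1]] <- 0
  out <- series
  out[[setdiff(names(out), "time_min")[1]]] <- shifted
  out
}

#' Dopaminergic input from the delayed effect-site concentration
#'
#' The Hill (sigmoid-Emax) law
#' `D = D0 + Dmax c^ND / (Dc50^ND + c^ND)`: `D` rises from the basal tone
#' `D0` towards `D0 + Dmax`, reaching the midpoint at `c = Dc50`; `ND`
#' sets the steepness (a large `ND` makes the response nearly
#' all-or-nothing).
#'
#' @param series A tibble with `time_min` and the delayed effect-site
#'   concentration (mg/l), non-negative.
#' @param pd A [pd_parameters()] object (fields `D0`, `Dmax`, `Dc50`,
#'   `ND` are used).
#' @return A tibble with columns `time_min` and `D`.
#' @export
dopaminergic_input <- function(series, pd) {
  check_series(series)
  stopifnot(inherits(pd, "pd_parameters"))
  cc <- series_values(series)
  if (any(cc < 0))
    abort("input error: effect-site concentration must be non-negative",
          class = "levotap_input_error")
  tibble::tibble(time_min = series_times(series),
                 D = hill_law(cc, pd$D0, pd$Dmax, pd$Dc50, pd$ND))
}

hill_law <- function(c, D0, Dmax, Dc50, ND) {
  # (c/Dc50)^ND form avoids overflow for large ND
  r <- (c / Dc50)^ND
  D0 + Dmax * r / (1 + r)
}

#' Dopaminergic input over time for a given PK/PD parameter set
#'
#' Convenience composition of the forward pipeline
#' plasma -> effect compartment -> pure delay -> Hill law, evaluated with
#' the analytic plasma solution on a dense internal grid.
#'
#' @inheritParams simulate_plasma
#' @param pd A [pd_parameters()] object.
#' @param times Output times (min).
#' @param grid_min Internal grid step (min).
#' @return A tibble with columns `time_min` and `D`.
#' @export
dopaminergic_series <- function(pk, pd, dose = dose_event(), times,
                                grid_min = 1) {
  stopifnot(inherits(pk, "pk_parameters"), inherits(pd, "pd_parameters"))
  terms <- pk_exp_terms(pk, dose)
  tg <- seq(0, ceiling(max(times) / grid_min) * grid_min, by = grid_min)
  c1 <- if (is.null(terms))
    simulate_plasma(pk, dose, tg)$conc_mg_l
  else
    eval_exp_terms(terms, tg)
  d_of_t(c1, tg, pd, times)
}

# shared dense-grid tail of the pipeline (also used by the fast objective)
d_of_t <- function(c1_dense, t_dense, pd, times) {
  h <- t_dense[2] - t_dense[1]
  c3 <- c(0, effect_step(c1_dense, pd$ke3, h))[seq_along(t_dense)]
  c3d <- approx(t_dense, c3, xout = times - pd$T, rule = 1)$y
  c3d[times - pd$T < t_dense[1]] <- 0
  tibble::tibble(time_min = times,
                 D = hill_law(pmax(c3d, 0), pd$D0, pd$Dmax, pd$Dc50, pd$ND))
}
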