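# Two-compartment LD kinetics with a first-order oral depot.
#
# States: depot A (mg), central concentration c1 (mg/l), peripheral
# concentration c2 (mg/l).  With the clearance convention (flux between
# compartments = clearance x source-compartment concentration):
#
#   A'  = -ka * A
#   V1 c1' = ka A - (k12 + ketot) c1 + k21 c2
#   V2 c2' = k12 c1 - k21 c2
#
# The system is linear; its solution is a sum of three exponentials whose
# rates are the eigenvalues of the coefficient matrix.

pk_matrix <- function(pk) {
  rbind(c(-pk$ka,            0,                          0),
        c(pk$ka / pk$V1, -(pk$k12 + pk$ketot) / pk$V1,  pk$k21 / pk$V1),
        c(0,              pk$k12 / pk$V2,              -pk$k21 / pk$V2))
}

# Exponential-mode decomposition of the depot/central/peripheral system:
# x_i(t) = sum_j coef[i, j] * exp(lambda[j] * t).  Used as the analytic
# fast path and as the closed-form oracle for the ODE integrator.
pk_exp_terms <- function(pk, dose = dose_event()) {
  A <- pk_matrix(pk)
  eg <- eigen(A)
  if (any(abs(Im(eg$values)) > 1e-9) ||
      min(abs(outer(Re(eg$values), Re(eg$values), "-"))[lower.tri(diag(3))]) <
        1e-10 * max(abs(eg$values)))
    return(NULL)  # (near-)degenerate modes: caller falls back to the ODE path
  lambda <- Re(eg$values)
  V <- Re(eg$vectors)
  x0 <- c(dose$amount_mg, 0, 0)
  w <- solve(V, x0)
  list(lambda = lambda, coef = V %*% diag(w, 3))
}

eval_exp_terms <- function(terms, times, row = 2) {
  E <- exp(outer(times, terms$lambda))
  as.vector(E %*% terms$coef[row, ])
}

#' Closed-form (tri-exponential) solution of the plasma model
#'
#' Analytic eigen-decomposition solution of the linear
#' depot/central/peripheral system.  Serves as an independent oracle for
#' [simulate_plasma()] and as the fast path inside the fitting routines.
#'
#' @inheritParams simulate_plasma
#' @return A tibble with columns `time_min`, `depot_mg`, `conc_mg_l`
#'   (central), `conc_peripheral_mg_l` and `eliminated_mg`.
#' @export
plasma_closed_form <- function(pk, dose = dose_event(), times) {
  stopifnot(inherits(pk, "pk_parameters"), inherits(dose, "dose_event"))
  validate_series_vectors(times, times)
  terms <- pk_exp_terms(pk, dose)
  if (is.null(terms))
    abort("degenerate kinetic modes: use simulate_plasma(method = \"ode\")",
          class = "levotap_invalid_parameter")
  t0 <- times - dose$time_min
  X <- sapply(1:3, function(i) {
    v <- eval_exp_terms(terms, pmax(t0, 0), row = i)
    ifelse(t0 < 0, 0, v)
  })
  elim <- pmax(dose$amount_mg - X[, 1] - pk$V1 * X[, 2] - pk$V2 * X[, 3], 0)
  tibble::tibble(time_min = times, depot_mg = X[, 1], conc_mg_l = X[, 2],
                 conc_peripheral_mg_l = X[, 3], eliminated_mg = elim)
}

#' Simulate LD plasma concentration after an oral dose
#'
#' Integrates the two-compartment system with a first-order oral depot
#' using an adaptive, stiff-capable solver (rtol 1e-8, atol 1e-10).  Total
#' mass (depot + dissolved + eliminated) is conserved to integrator
#' tolerance.
#'
#' @param pk A [pk_parameters()] object.
#' @param dose A [dose_event()].
#' @param times Output times (min), strictly increasing.
#' @param full If `TRUE`, return all compartment states and the cumulative
#'   eliminated mass; otherwise only the central concentration.
#' @return A tibble with `time_min` and `conc_mg_l` (plus the other states
#'   when `full = TRUE`).
#' @examples
#' pk <- pk_parameters(k12 = 1.2, k21 = 0.9, ketot = 2.4)
#' simulate_plasma(pk, dose_event(100), times = seq(0, 180, by = 15))
#' @export
simulate_plasma <- function(pk, dose = dose_event(), times, full = FALSE) {
  stopifnot(inherits(pk, "pk_parameters"), inherits(dose, "dose_event"))
  validate_series_vectors(times, times)
  if (any(times < dose$time_min) && any(times >= dose$time_min))
    stopifnot(all(times >= 0))
  t_rel <- times - dose$time_min
  tt <- sort(unique(c(0, t_rel[t_rel >= 0])))
  y0 <- c(A = dose$amount_mg, c1 = 0, c2 = 0, elim = 0)
  deriv <- function(t, y, p) {
    list(c(-pk$ka * y[1],
           (pk$ka * y[1] - (pk$k12 + pk$ketot) * y[2] + pk$k21 * y[3]) / pk$V1,
           (pk$k12 * y[2] - pk$k21 * y[3]) / pk$V2,
           pk$ketot * y[2]))
  }
  sol <- deSolve::lsoda(y0, tt, deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  idx <- match(pmax(t_rel, 0), tt)
  get <- function(col) ifelse(t_rel < 0, 0, sol[idx, col])
  out <- tibble::tibble(time_min = times, conc_mg_l = get("c1"))
  if (full) {
    out$depot_mg <- get("A")
    out$conc_peripheral_mg_l <- get("c2")
    out$eliminated_mg <- get("elim")
  }
  out
}

#' Fit the three plasma kinetic parameters of one patient
#'
#' Minimises the sum of squared errors between the modelled and measured
#' central-compartment concentration with the derivative-free Nelder-Mead
#' simplex, from the single standard initial guess
#' (k12 = 1.5, k21 = 1.5, ketot = 3 l/min).  Positivity is enforced by
#' optimising the log-parameters.  The fit is deterministic.
#'
#' @param observed A tibble with columns `time_min` and `conc_mg_l`
#'   (>= 4 samples spanning rise and decay).
#' @param dose A [dose_event()].
#' @param init Initial guess for `(k12, k21, ketot)` (l/min).
#' @param V1,V2,ka Fixed prototypical constants, passed to
#'   [pk_parameters()].
#' @param maxit Maximum simplex iterations.
#' @return An object of class `pk_fit`: estimated [pk_parameters()], final
#'   `sse`, `r2`, and a `converged` flag (non-convergence is flagged, not
#'   an error).
#' @examples
#' pk <- pk_parameters(k12 = 1.2, k21 = 0.9, ketot = 2.4)
#' obs <- simulate_plasma(pk, times = c(0, 15, 30, 45, 60, 75, 90, 120, 150, 180))
#' fit <- fit_pk(obs)
#' glance(fit)
#' @export
fit_pk <- function(observed, dose = dose_event(), init = c(1.5, 1.5, 3),
                   V1 = 45, V2 = 90, ka = 0.07, maxit = 2000) {
  check_series(observed)
  tt <- series_times(observed)
  cc <- series_values(observed)
  if (length(tt) < 4)
    abort("input error: need at least 4 plasma samples", class = "levotap_input_error")
  if (all(cc == 0))
    abort("degenerate-data: all plasma observations are zero",
          class = "levotap_degenerate_data")
  obj <- function(z) {
    k <- exp(z)
    pk <- structure(list(k12 = k[1], k21 = k[2], ketot = k[3],
                         V1 = V1, V2 = V2, ka = ka), class = "pk_parameters")
    terms <- pk_exp_terms(pk, dose)
    if (is.null(terms)) return(1e12)
    pred <- eval_exp_terms(terms, pmax(tt - dose$time_min, 0))
    pred[tt < dose$time_min] <- 0
    sum((pred - cc)^2)
  }
  opt <- optim(log(init), obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-8))
  # polish once from the solution: standard simplex restart
  opt2 <- optim(opt$par, obj, method = "Nelder-Mead",
                control = list(maxit = maxit, reltol = 1e-8))
  if (opt2$value < opt$value) opt <- opt2
  k <- exp(opt$par)
  pk <- pk_parameters(k12 = k[1], k21 = k[2], ketot = k[3],
                      V1 = V1, V2 = V2, ka = ka)
  pred <- plasma_closed_form(pk, dose, tt)$conc_mg_l
  r2 <- if (sd(cc) > 0) compute_r2(pred, cc) else NA_real_
  structure(list(parameters = pk, sse = opt$value, r2 = r2,
                 converged = opt$convergence == 0,
                 iterations = unname(opt$counts[1]), dose = dose),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("<pk_fit>  SSE =", format(x$sse, digits = 4),
      " R2 =", format(x$r2, digits = 4),
      if (!x$converged) " [not converged]" else "", "\n")
  print(x$parameters)
  invisible(x)
}
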