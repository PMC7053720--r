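# broom-style tidiers and ggplot2 autoplot methods for the fitted
# objects and result types.

#' @method tidy pk_fit
#' @export
tidy.pk_fit <- function(x, ...) {
  p <- x$parameters
  tibble::tibble(term = c("k12", "k21", "ketot"),
                 estimate = c(p$k12, p$k21, p$ketot),
                 unit = "l/min")
}

#' @method glance pk_fit
#' @export
glance.pk_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, r2 = x$r2, converged = x$converged,
                 iterations = x$iterations)
}

#' @method tidy pd_fit
#' @export
tidy.pd_fit <- function(x, ...) {
  p <- x$parameters
  tibble::tibble(term = c("ke3", "T", "D0", "Dmax", "Dc50", "ND"),
                 estimate = c(p$ke3, p$T, p$D0, p$Dmax, p$Dc50, p$ND),
                 unit = c("1/min", "min", "", "", "mg/l", ""))
}

#' @method glance pd_fit
#' @export
glance.pd_fit <- function(x, ...) {
  tibble::tibble(cost = x$cost, r2 = x$r2, n_restarts = x$n_restarts,
                 best_restart = x$best_restart, seed = x$seed,
                 converged = x$converged)
}

#' @method autoplot frequency_curve
#' @export
autoplot.frequency_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$D, y = .data$taps_per_min)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "dopaminergic input D",
                  y = "steady-state tapping frequency (taps/min)") +
    ggplot2::theme_minimal()
}

#' @method autoplot patient_record
#' @export
autoplot.patient_record <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(object$plasma, value = "conc_mg_l"),
                  panel = "plasma LD (mg/l)"),
    dplyr::mutate(dplyr::rename(object$tapping, value = "taps_per_min"),
                  panel = "tapping (taps/min)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(title = paste0(object$id, " (", object$group, ")"),
                  x = "time after dose (min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Observed versus fitted tapping trajectory
#'
#' @param fit A `pd_fit`.
#' @param patient The patient record the fit was produced from.
#' @param times Dense evaluation grid for the model curve (min).
#' @return A ggplot object.
#' @export
plot_pd_fit <- function(fit, patient, times = seq(0, 240, by = 2)) {
  stopifnot(inherits(fit, "pd_fit"))
  model <- tibble::tibble(
    time_min = times,
    taps_per_min = curve_interp(fit$curve,
      dopaminergic_series(fit$pk, fit$parameters, fit$dose, times)$D))
  ggplot2::ggplot(model, ggplot2::aes(x = .data$time_min,
                                      y = .data$taps_per_min)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = patient$tapping, colour = "firebrick") +
    ggplot2::labs(x = "time after dose (min)", y = "tapping (taps/min)",
                  title = sprintf("%s: R2 = %.3f", patient$id, fit$r2)) +
    ggplot2::theme_minimal()
}

#' @method autoplot training_experiment
#' @export
autoplot.training_experiment <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("untrained", "trained"),
                              names_to = "condition",
                              values_to = "taps_per_min")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min,
                                     y = .data$taps_per_min,
                                     colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = attr(object, "baseline"),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = attr(object, "session_time_min"),
                        linetype = "dotted") +
    ggplot2::labs(x = "time after dose (min)", y = "tapping (taps/min)") +
    ggplot2::theme_minimal()
}
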