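# Clinical response metrics and the two-group comparison of estimated
# parameters.  Onset of a clinically significant motor response is a
# tapping rate at least 15 percent above the pre-dose baseline; duration
# is the time from onset until the rate falls back below that same
# threshold; fluctuating patients return within the 4-hour test, stable
# patients do not.

onset_threshold <- 1.15

#' Latency to onset of the motor response
#'
#' Earliest sample time at which the tapping rate reaches at least 115
#' percent of the pre-dose baseline (the boundary value qualifies);
#' `NA` if the threshold is never reached.
#'
#' @param tapping A tibble with `time_min` and `taps_per_min`.
#' @param baseline Pre-dose tapping rate (> 0).
#' @return Minutes, or `NA_real_`.
#' @export
latency_to_onset <- function(tapping, baseline) {
  check_series(tapping)
  if (!is.numeric(baseline) || baseline <= 0)
    abort("input error: baseline must be positive", class = "levotap_input_error")
  tt <- series_times(tapping)
  vv <- series_values(tapping)
  i <- which(vv >= onset_threshold * baseline)
  if (length(i) == 0) NA_real_ else tt[i[1]]
}

#' Duration of the motor response
#'
#' Time from onset until the tapping rate first falls back below 115
#' percent of baseline; `NA` (right-censored) if no return occurs within
#' the observation window.
#'
#' @inheritParams latency_to_onset
#' @return Minutes, or `NA_real_` (censored).
#' @export
effect_duration <- function(tapping, baseline) {
  lat <- latency_to_onset(tapping, baseline)
  if (is.na(lat))
    abort("undefined duration: no onset of response",
          class = "levotap_undefined_duration")
  tt <- series_times(tapping)
  vv <- series_values(tapping)
  i <- which(tt > lat & vv < onset_threshold * baseline)
  if (length(i) == 0) NA_real_ else tt[i[1]] - lat
}

#' Classify the LD response as stable or fluctuating
#'
#' Fluctuating if and only if the response returns to baseline (the
#' effect duration is defined) within the observation window; stable
#' otherwise.  A series that never shows an onset is classified stable
#' and carries a `no_onset` warning attribute.
#'
#' @inheritParams latency_to_onset
#' @param baseline Pre-dose tapping rate; defaults to the t = 0 sample
#'   (or the earliest sample).
#' @return `"stable"` or `"fluctuating"` (character), with attribute
#'   `no_onset`.
#' @export
classify_response <- function(tapping, baseline = NULL) {
  check_series(tapping)
  if (is.null(baseline)) {
    tt <- series_times(tapping)
    baseline <- series_values(tapping)[if (any(tt == 0)) which(tt == 0)[1] else 1]
  }
  lat <- latency_to_onset(tapping, baseline)
  if (is.na(lat)) {
    warn("no onset of response; classified stable",
         class = "levotap_no_onset_warning")
    return(structure("stable", no_onset = TRUE))
  }
  dur <- effect_duration(tapping, baseline)
  structure(if (is.na(dur)) "stable" else "fluctuating", no_onset = FALSE)
}

#' All response metrics of one tapping series
#'
#' @inheritParams classify_response
#' @return A one-row tibble: `baseline`, `latency_min`, `duration_min`,
#'   `classification`, `no_onset`.
#' @export
response_metrics <- function(tapping, baseline = NULL) {
  check_series(tapping)
  if (is.null(baseline)) {
    tt <- series_times(tapping)
    baseline <- series_values(tapping)[if (any(tt == 0)) which(tt == 0)[1] else 1]
  }
  lat <- latency_to_onset(tapping, baseline)
  dur <- if (is.na(lat)) NA_real_ else effect_duration(tapping, baseline)
  cls <- suppressWarnings(classify_response(tapping, baseline))
  tibble::tibble(baseline = baseline, latency_min = lat, duration_min = dur,
                 classification = as.character(cls),
                 no_onset = isTRUE(attr(cls, "no_onset")))
}

#' Compare estimated parameters between two patient groups
#'
#' Two-sided exact Wilcoxon rank-sum test per parameter (the groups are
#' independent samples), with a fixed Bonferroni factor of 9 - the nine
#' estimated kinetic and dynamic parameters - applied as
#' `p_adj = min(1, 9 p)`.
#'
#' @param params_group1,params_group2 Data frames with one row per
#'   patient and one numeric column per parameter (>= 3 rows each).
#' @param parameters Columns to compare; defaults to the shared numeric
#'   columns.
#' @param bonferroni_factor Multiplicity correction factor.
#' @return A tibble: `parameter`, `median_g1`, `median_g2`, `p_raw`,
#'   `p_bonferroni`.
#' @export
compare_groups <- function(params_group1, params_group2, parameters = NULL,
                           bonferroni_factor = 9) {
  if (nrow(params_group1) < 3 || nrow(params_group2) < 3)
    abort("input error: each group needs at least 3 patients",
          class = "levotap_input_error")
  if (is.null(parameters)) {
    num1 <- names(params_group1)[vapply(params_group1, is.numeric, TRUE)]
    num2 <- names(params_group2)[vapply(params_group2, is.numeric, TRUE)]
    parameters <- intersect(num1, num2)
  }
  purrr::map_dfr(parameters, function(p) {
    x <- params_group1[[p]]
    y <- params_group2[[p]]
    pw <- suppressWarnings(wilcox.test(x, y, exact = TRUE))$p.value
    tibble::tibble(parameter = p, median_g1 = median(x), median_g2 = median(y),
                   p_raw = pw, p_bonferroni = min(1, bonferroni_factor * pw))
  })
}

#' Omnibus K2 normality test
#'
#' D'Agostino-Pearson omnibus test combining the transformed sample
#' skewness (D'Agostino 1970) and kurtosis (Anscombe-Glynn 1983) into
#' `K2 = Z1^2 + Z2^2`, referred to a chi-squared distribution with 2
#' degrees of freedom.  Used to justify the nonparametric group
#' comparison.
#'
#' @param x Numeric sample, n >= 8.
#' @return A one-row tibble: `statistic`, `p_value`, `z_skewness`,
#'   `z_kurtosis`, `n`.
#' @export
gaussianity_check <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8)
    abort("input error: the omnibus K2 test needs n >= 8",
          class = "levotap_input_error")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2
  # skewness: D'Agostino (1970) normalising transformation
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983)
  Eg2 <- 3 * (n - 1) / (n + 1)
  Vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eg2) / sqrt(Vg2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Z1^2 + Z2^2
  tibble::tibble(statistic = K2, p_value = pchisq(K2, 2, lower.tail = FALSE),
                 z_skewness = Z1, z_kurtosis = Z2, n = n)
}
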