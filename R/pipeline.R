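# End-to-end cohort pipeline: stage-1 plasma fit, stage-2 tapping fit and
# the two-group statistics, with per-patient fault isolation.

#' Fit one patient end to end
#'
#' @param patient A `patient_record`.
#' @param config A `run_config` list (see [default_run_config()]).
#' @param curve A precomputed `frequency_curve` (computed from the
#'   configuration when `NULL`).
#' @param seed Seed for the restart draws.
#' @return A list with `id`, `group`, `pk_fit`, `pd_fit` and `metrics`.
#' @export
fit_patient <- function(patient, config = default_run_config(), curve = NULL,
                        seed = config$seed) {
  stopifnot(inherits(patient, "patient_record"))
  if (is.null(curve))
    curve <- steady_state_frequency_curve(config_bg(config))
  pkf <- fit_pk(patient$plasma, dose = patient$dose,
                init = config$pk$initial_guess,
                V1 = config$pk$V1_l, V2 = config$pk$V2_l,
                ka = config$pk$ka_per_min)
  pdf <- fit_pd(patient, pkf, curve = curve,
                n_restarts = config$estimation$n_restarts, seed = seed,
                k = config$estimation$k, ranges = config$estimation$ranges,
                dose = patient$dose)
  list(id = patient$id, group = patient$group, pk_fit = pkf, pd_fit = pdf,
       metrics = response_metrics(patient$tapping))
}

#' Run the full estimation pipeline over a cohort
#'
#' Fits every patient (plasma kinetics first, then the six
#' pharmacodynamic parameters), assembles the results table, and - when
#' both labelled groups have at least 3 successfully fitted patients -
#' compares the nine estimated parameters between groups with the exact
#' rank-sum test and Bonferroni correction.  A failure on one patient is
#' recorded and the pipeline continues with the rest.  Deterministic
#' given `config$seed`.
#'
#' @param patients A `patient_cohort`, list of `patient_record`s, or a
#'   directory of patient CSV files.
#' @param config A `run_config`.
#' @param output_dir If non-`NULL`, `results.csv` and `stats.csv` are
#'   written there.
#' @return A list: `results` (tibble), `stats` (tibble or `NULL`),
#'   `errors` (named list of failure messages), `fits`.
#' @export
run_pipeline <- function(patients, config = default_run_config(),
                         output_dir = NULL) {
  if (is.character(patients)) {
    files <- sort(list.files(patients, pattern = "\\.csv$", full.names = TRUE))
    files <- files[!grepl("ground_truth", files)]
    patients <- lapply(files, function(f)
      tryCatch(read_patient_csv(f), error = function(e) {
        structure(list(file = f, message = conditionMessage(e)),
                  class = "levotap_failed_patient")
      }))
  }
  curve <- steady_state_frequency_curve(config_bg(config))
  errors <- list()
  fits <- list()
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    if (inherits(p, "levotap_failed_patient")) {
      errors[[basename(p$file)]] <- p$message
      next
    }
    res <- tryCatch(
      fit_patient(p, config, curve, seed = derive_seed(config$seed, i)),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[if (inherits(p, "patient_record")) p$id else paste0("patient", i)]] <-
        conditionMessage(res)
    } else {
      fits[[length(fits) + 1]] <- res
    }
  }
  if (length(errors) > 0)
    warn(paste0(length(errors), " patient(s) failed to fit"),
         class = "levotap_pipeline_warning")
  if (length(fits) == 0)
    abort("pipeline failure: no patient could be fitted",
          class = "levotap_pipeline_error")
  results <- fit_results_table(fits)
  g1 <- dplyr::filter(results, .data$group == "stable")
  g2 <- dplyr::filter(results, .data$group == "fluctuating")
  stats_tab <- NULL
  if (nrow(g1) >= 3 && nrow(g2) >= 3) {
    par_cols <- c("k12", "k21", "ketot", "ke3", "D0", "T", "Dmax", "Dc50", "ND")
    stats_tab <- compare_groups(g1[par_cols], g2[par_cols],
                                bonferroni_factor = config$stats$bonferroni_factor)
  } else {
    message("group comparison skipped: fewer than 3 patients per labelled group")
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(results, file.path(output_dir, "results.csv"))
    if (!is.null(stats_tab))
      readr::write_csv(stats_tab, file.path(output_dir, "stats.csv"))
  }
  list(results = results, stats = stats_tab, errors = errors, fits = fits)
}
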