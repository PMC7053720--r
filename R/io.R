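# File formats: one CSV per patient (columns time_min, plasma_mg_l,
# taps_per_min; blank cells = not sampled at that time), a wide results
# CSV with one row per fitted patient, and a YAML run configuration with
# shipped defaults and strict key checking.

#' Read a patient CSV
#'
#' Expected columns: `time_min`, `plasma_mg_l`, `taps_per_min` (header
#' mandatory; decimal point, comma separator).  Blank cells mark samples
#' not taken at that time; each series keeps only its sampled times.
#'
#' @param path File path.
#' @param id Patient identifier; defaults to the file name.
#' @param group Group label (`"stable"`, `"fluctuating"` or
#'   `"unknown"`).
#' @param dose A [dose_event()].
#' @return A `patient_record` (without ground truth).
#' @export
read_patient_csv <- function(path, id = NULL, group = "unknown",
                             dose = dose_event()) {
  if (!file.exists(path))
    abort(paste0("file not found: ", path), class = "levotap_io_error")
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("time_min", "plasma_mg_l", "taps_per_min")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    abort(paste0("format error: missing required column(s): ",
                 paste(miss, collapse = ", ")),
          class = "levotap_format_error")
  num <- function(col) {
    x <- trimws(raw[[col]])
    x[x == ""] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad) > 0)
      abort(paste0("format error: non-numeric value in column `", col,
                   "`, row ", bad[1]),
            class = "levotap_format_error")
    v
  }
  tt <- num("time_min")
  if (anyNA(tt))
    abort("format error: blank `time_min` cell", class = "levotap_format_error")
  pl <- num("plasma_mg_l")
  tp <- num("taps_per_min")
  keep_p <- !is.na(pl)
  keep_t <- !is.na(tp)
  plasma <- tibble::tibble(time_min = tt[keep_p], conc_mg_l = pl[keep_p])
  tapping <- tibble::tibble(time_min = tt[keep_t], taps_per_min = tp[keep_t])
  if (nrow(plasma) > 0) check_series(plasma)
  if (nrow(tapping) > 0) check_series(tapping)
  structure(list(id = if (is.null(id)) sub("\\.csv$", "", basename(path)) else id,
                 group = group, dose = dose, plasma = plasma,
                 tapping = tapping, ground_truth = NULL),
            class = "patient_record")
}

#' Write a patient record to CSV
#'
#' @param patient A `patient_record`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_patient_csv <- function(patient, path) {
  stopifnot(inherits(patient, "patient_record"))
  all_t <- sort(unique(c(patient$plasma$time_min, patient$tapping$time_min)))
  out <- tibble::tibble(
    time_min = all_t,
    plasma_mg_l = patient$plasma$conc_mg_l[match(all_t, patient$plasma$time_min)],
    taps_per_min = patient$tapping$taps_per_min[match(all_t, patient$tapping$time_min)])
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Collect per-patient fits into a results table
#'
#' @param fits A non-empty list; each element a list with `id`, `group`,
#'   `pk_fit` (a `pk_fit`) and `pd_fit` (a `pd_fit`).
#' @return A tibble with one row per patient: the nine estimates, cost,
#'   `r2_LD`, `r2_tapping`, `best_restart` and `seed`.
#' @export
fit_results_table <- function(fits) {
  if (length(fits) == 0)
    abort("input error: empty fit list", class = "levotap_input_error")
  purrr::map_dfr(fits, function(f) {
    pk <- f$pk_fit$parameters
    pd <- f$pd_fit$parameters
    tibble::tibble(id = f$id, group = f$group,
                   k12 = pk$k12, k21 = pk$k21, ketot = pk$ketot,
                   ke3 = pd$ke3, D0 = pd$D0, T = pd$T, Dmax = pd$Dmax,
                   Dc50 = pd$Dc50, ND = pd$ND,
                   cost = f$pd_fit$cost, r2_LD = f$pk_fit$r2,
                   r2_tapping = f$pd_fit$r2,
                   best_restart = f$pd_fit$best_restart,
                   seed = f$pd_fit$seed)
  })
}

#' Write fit results to CSV
#'
#' @inheritParams fit_results_table
#' @param path Output file.
#' @return The results tibble, invisibly.
#' @export
write_fit_results <- function(fits, path) {
  tab <- if (is.data.frame(fits)) fits else fit_results_table(fits)
  readr::write_csv(tab, path)
  invisible(tab)
}

#' Shipped run-configuration defaults
#'
#' Nested list mirroring the configuration file sections: `pk` (volumes,
#' absorption rate, initial guess), `pd` (internal grid, inert `v3_l`),
#' `network` (all [bg_config()] fields), `synth` (archetype intervals and
#' noise), `estimation` (restarts, ranges, cost weight `k`), `stats`
#' (Bonferroni factor), plus the global `seed`.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    pk = list(V1_l = 45, V2_l = 90, ka_per_min = 0.07,
              initial_guess = c(1.5, 1.5, 3)),
    pd = list(internal_grid_min = 1, v3_l = 30),
    network = unclass(bg_config()),
    synth = list(n_stable = 13, n_fluctuating = 13,
                 plasma_cv = 0.08, tapping_sd = 7),
    estimation = list(n_restarts = 10, k = 10,
                      ranges = list(ke3 = c(0.005, 0.2), T = c(0, 60),
                                    Dmax = c(0.2, 5), Dc50 = c(0.1, 3),
                                    ND = c(1, 15))),
    stats = list(bonferroni_factor = 9),
    seed = 1), class = "run_config")
}

#' Read a run configuration file
#'
#' YAML key/value sections merged over [default_run_config()]; unknown
#' keys are rejected.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_strict <- function(base, upd, prefix = "") {
    for (nm in names(upd)) {
      if (!nm %in% names(base))
        abort(paste0("unknown configuration key: ", prefix, nm),
              class = "levotap_config_error")
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        merge_strict(base[[nm]], upd[[nm]], paste0(prefix, nm, "."))
      else upd[[nm]]
    }
    base
  }
  structure(merge_strict(unclass(cfg), user), class = "run_config")
}

config_bg <- function(config) {
  do.call(bg_config, config$network)
}
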