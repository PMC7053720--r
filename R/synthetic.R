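# Synthetic patients with the clinical sampling protocol: plasma drawn
# pre-dose, every 15 min to 90 min, then half-hourly to 180 min; tapping
# assessed to 240 min.  Two response archetypes reproduce the cohort
# structure: "fluctuating" patients carry a faster effect-site removal
# (ke3) and a steeper Hill slope (ND) than "stable" patients, which makes
# their response return to baseline within the 4-hour window.

plasma_schedule <- c(0, 15, 30, 45, 60, 75, 90, 120, 150, 180)
tapping_schedule <- c(plasma_schedule, 210, 240)

#' Response archetype: parameter intervals and noise model
#'
#' The shared pharmacokinetic and most pharmacodynamic intervals are
#' common to both archetypes; `ke3` and `ND` are sampled from disjoint
#' intervals lying strictly higher for the fluctuating archetype.
#' Measurement noise is multiplicative on plasma (coefficient of
#' variation) and additive on tapping (taps/min, clipped at 0).
#'
#' @param label `"stable"` or `"fluctuating"`.
#' @param plasma_cv,tapping_sd Noise magnitudes.
#' @return An object of class `archetype`.
#' @export
archetype <- function(label = c("stable", "fluctuating"),
                      plasma_cv = 0.08, tapping_sd = 7) {
  label <- match.arg(label)
  shared <- list(k12 = c(0.5, 3), k21 = c(0.5, 3), ketot = c(1, 5),
                 T = c(5, 30), Dmax = c(0.5, 2), D0 = c(0.3, 0.8),
                 Dc50 = c(0.3, 1))
  per_label <- if (label == "stable")
    list(ke3 = c(0.01, 0.03), ND = c(1.5, 4))
  else
    list(ke3 = c(0.05, 0.15), ND = c(6, 12))
  structure(list(label = label, ranges = c(shared, per_label),
                 noise = list(plasma_cv = plasma_cv,
                              tapping_sd = tapping_sd)),
            class = "archetype")
}

#' Draw one ground-truth parameter set from an archetype
#'
#' Independent log-uniform draws within the archetype intervals.
#'
#' @param arch An [archetype()].
#' @param seed RNG seed (`NULL` = current stream).
#' @return A list with elements `pk` ([pk_parameters()]) and `pd`
#'   ([pd_parameters()]).
#' @export
sample_parameters <- function(arch, seed = NULL) {
  stopifnot(inherits(arch, "archetype"))
  local_seed(seed, {
    d <- lapply(arch$ranges, function(r) exp(runif(1, log(r[1]), log(r[2]))))
    list(pk = pk_parameters(k12 = d$k12, k21 = d$k21, ketot = d$ketot),
         pd = pd_parameters(ke3 = d$ke3, T = d$T, D0 = d$D0, Dmax = d$Dmax,
                            Dc50 = d$Dc50, ND = d$ND))
  })
}

#' Generate one synthetic patient record
#'
#' Samples ground-truth parameters, runs the full forward pipeline
#' (plasma, effect site, delay, Hill law, frequency curve) and samples
#' the model curves at the clinical schedule with measurement noise.
#'
#' @param arch An [archetype()].
#' @param seed RNG seed of this patient.
#' @param config A [bg_config()].
#' @param curve Optional precomputed `frequency_curve`.
#' @param id Patient identifier.
#' @param dose A [dose_event()].
#' @return An object of class `patient_record`: `id`, `group`, `dose`,
#'   `plasma` (tibble, mg/l), `tapping` (tibble, taps/min), and the
#'   `ground_truth` parameter list.
#' @examples
#' p <- generate_patient(archetype("fluctuating"), seed = 7)
#' p$tapping
#' @export
generate_patient <- function(arch, seed = NULL,
                             config = default_bg_config(), curve = NULL,
                             id = paste0(substr(arch$label, 1, 1), seed),
                             dose = dose_event()) {
  stopifnot(inherits(arch, "archetype"))
  if (is.null(curve)) curve <- steady_state_frequency_curve(config)
  truth <- sample_parameters(arch, seed)
  c1 <- plasma_closed_form(truth$pk, dose, plasma_schedule)$conc_mg_l
  fmod <- curve_interp(curve, dopaminergic_series(truth$pk, truth$pd, dose,
                                                  tapping_schedule)$D)
  noisy <- local_seed(if (is.null(seed)) NULL else derive_seed(seed, 1), {
    plasma <- pmax(c1 * (1 + rnorm(length(c1), 0, arch$noise$plasma_cv)), 0)
    tapping <- pmax(fmod + rnorm(length(fmod), 0, arch$noise$tapping_sd), 0)
    list(plasma = plasma, tapping = tapping)
  })
  structure(list(id = id, group = arch$label, dose = dose,
                 plasma = tibble::tibble(time_min = plasma_schedule,
                                         conc_mg_l = noisy$plasma),
                 tapping = tibble::tibble(time_min = tapping_schedule,
                                          taps_per_min = noisy$tapping),
                 ground_truth = truth),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s (%s): %d plasma, %d tapping samples%s\n",
              x$id, x$group, nrow(x$plasma), nrow(x$tapping),
              if (!is.null(x$ground_truth)) ", ground truth attached" else ""))
  invisible(x)
}

#' Generate a synthetic two-group cohort
#'
#' Per-patient seeds are derived deterministically from `master_seed`, so
#' the same master seed always reproduces the identical cohort.
#'
#' @param n_stable,n_fluctuating Group sizes (the clinical cohort is
#'   13 + 13).
#' @param master_seed Cohort seed.
#' @param config A [bg_config()].
#' @param plasma_cv,tapping_sd Noise magnitudes passed to [archetype()].
#' @return A list of [generate_patient()] records of class
#'   `patient_cohort`.
#' @export
generate_cohort <- function(n_stable = 13, n_fluctuating = 13,
                            master_seed = 1,
                            config = default_bg_config(),
                            plasma_cv = 0.08, tapping_sd = 7) {
  if (n_stable < 1 || n_fluctuating < 1)
    abort("input error: group sizes must be >= 1", class = "levotap_input_error")
  curve <- steady_state_frequency_curve(config)
  mk <- function(label, n, offset) {
    arch <- archetype(label, plasma_cv, tapping_sd)
    lapply(seq_len(n), function(i)
      generate_patient(arch, seed = derive_seed(master_seed, offset + i),
                       config = config, curve = curve,
                       id = sprintf("%s%02d", toupper(substr(label, 1, 1)), i)))
  }
  structure(c(mk("stable", n_stable, 0),
              mk("fluctuating", n_fluctuating, 1000)),
            class = "patient_cohort")
}

#' @export
print.patient_cohort <- function(x, ...) {
  groups <- table(vapply(x, `[[`, "", "group"))
  cat("<patient_cohort>",
      paste(names(groups), groups, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
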