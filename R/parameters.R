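#' Pharmacokinetic parameters of the two-compartment oral LD model
#'
#' The three rate parameters `k12`, `k21` and `ketot` are the quantities
#' estimated per patient.  They carry a clearance dimension (l/min): the
#' drug flux between compartments equals clearance times the concentration
#' of the source compartment.  The compartment volumes `V1`, `V2` and the
#' first-order oral absorption rate `ka` are prototypical constants, never
#' altered by fitting.
#'
#' @param k12,k21 Central-to-peripheral and peripheral-to-central transfer
#'   clearances (l/min).
#' @param ketot Total body elimination clearance from the central
#'   compartment (l/min).
#' @param V1,V2 Central and peripheral distribution volumes (l).
#' @param ka First-order absorption rate from the oral depot (1/min).
#' @return An object of class `pk_parameters`.
#' @examples
#' pk_parameters()  # the standard initial guess
#' @export
pk_parameters <- function(k12 = 1.5, k21 = 1.5, ketot = 3,
                          V1 = 45, V2 = 90, ka = 0.07) {
  x <- list(k12 = k12, k21 = k21, ketot = ketot, V1 = V1, V2 = V2, ka = ka)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      abort(paste0("invalid-parameter: `", nm, "` must be a single positive number"),
            class = "levotap_invalid_parameter")
  }
  structure(x, class = "pk_parameters")
}

#' Pharmacodynamic parameters: effect compartment, delay and Hill law
#'
#' @param ke3 Drug removal rate from the effect compartment (1/min).
#' @param T Pure delay between effect-site concentration and motor effect
#'   (min).
#' @param D0 Basal dopaminergic input immediately before LD administration
#'   (dimensionless).
#' @param Dmax Maximum drug-induced increment of the dopaminergic input
#'   (dimensionless).
#' @param Dc50 Effect-site concentration producing half of `Dmax` (mg/l).
#' @param ND Hill coefficient; sets the steepness of the
#'   concentration-effect relationship.
#' @return An object of class `pd_parameters`.
#' @examples
#' pd_parameters(ke3 = 0.02, T = 15, D0 = 0.5, Dmax = 1, Dc50 = 0.5, ND = 3)
#' @export
pd_parameters <- function(ke3, T, D0, Dmax, Dc50, ND) {
  x <- list(ke3 = ke3, T = T, D0 = D0, Dmax = Dmax, Dc50 = Dc50, ND = ND)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      abort(paste0("invalid-parameter: `", nm, "` must be a single finite number"),
            class = "levotap_invalid_parameter")
  }
  if (x$ke3 <= 0 || x$Dmax <= 0 || x$Dc50 <= 0 || x$ND <= 0)
    abort("invalid-parameter: ke3, Dmax, Dc50 and ND must be strictly positive",
          class = "levotap_invalid_parameter")
  if (x$T < 0 || x$D0 < 0)
    abort("invalid-parameter: T and D0 must be non-negative",
          class = "levotap_invalid_parameter")
  structure(x, class = "pd_parameters")
}

#' A single oral LD dose event
#'
#' @param amount_mg LD mass (mg); the clinical protocol uses a 100 mg
#'   LD (with 25 mg benserazide) fasting morning dose.
#' @param time_min Administration time (min); 0 for the single-dose
#'   protocol.
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(amount_mg = 100, time_min = 0) {
  if (!is.numeric(amount_mg) || length(amount_mg) != 1 ||
      !is.finite(amount_mg) || amount_mg < 0)
    abort("invalid-parameter: `amount_mg` must be a single non-negative number",
          class = "levotap_invalid_parameter")
  structure(list(amount_mg = amount_mg, time_min = time_min),
            class = "dose_event")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("<pk_parameters>\n")
  cat(sprintf("  k12 = %.4g  k21 = %.4g  ketot = %.4g l/min\n",
              x$k12, x$k21, x$ketot))
  cat(sprintf("  V1 = %.4g l  V2 = %.4g l  ka = %.4g 1/min (fixed)\n",
              x$V1, x$V2, x$ka))
  invisible(x)
}

#' @export
print.pd_parameters <- function(x, ...) {
  cat("<pd_parameters>\n")
  cat(sprintf("  ke3 = %.4g 1/min  T = %.4g min  D0 = %.4g\n",
              x$ke3, x$T, x$D0))
  cat(sprintf("  Dmax = %.4g  Dc50 = %.4g mg/l  ND = %.4g\n",
              x$Dmax, x$Dc50, x$ND))
  invisible(x)
}

as_tibble_params <- function(x) {
  tibble::as_tibble(unclass(x)[!names(x) %in% c("V1", "V2", "ka")])
}
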