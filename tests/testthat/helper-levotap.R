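# Shared fixtures: everything is generated in code at test time.

the_curve <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- steady_state_frequency_curve()
    cache
  }
})

random_pk <- function() {
  pk_parameters(k12 = exp(runif(1, log(0.5), log(3))),
                k21 = exp(runif(1, log(0.5), log(3))),
                ketot = exp(runif(1, log(1), log(5))))
}

quiet_classify <- function(tapping, baseline = NULL) {
  suppressWarnings(as.character(classify_response(tapping, baseline)))
}

clinical_times <- c(0, 15, 30, 45, 60, 75, 90, 120, 150, 180)

# fixed samples whose omnibus K2 statistic was computed with an
# independent reference implementation (frozen expected values in
# test-cohort.R)
normal_fixture <- function() c(10.612969, 10.076635, 8.184411, 8.558601, 7.335836, 14.429948, 9.531849, 12.928137, 9.363253, 8.647125, 13.861046, 8.573833, 12.145384, 10.614298, 9.826708, 9.988079, 7.623192, 9.574460, 12.595418, 10.111001, 11.453738, 10.742959, 11.223338, 10.022126, 9.204564, 12.328770, 11.140427, 7.657938, 13.172364, 10.935436, 9.874844, 10.052364, 13.949667, 10.413208, 12.656041, 7.649117, 8.972835, 11.616297, 8.836438, 9.943882)

exp_fixture <- function() c(0.661968, 5.627836, 0.390926, 0.034724, 0.456598, 0.353343, 0.250110, 0.952235, 2.387229, 0.090448, 1.520629, 0.289706, 0.233971, 0.016907, 0.809074, 1.322728, 0.527790, 0.257119, 0.417818, 0.023456, 0.738220, 0.844834, 0.093670, 1.626706, 0.684131, 1.711159, 0.183327, 2.774260, 0.631884, 1.030074, 0.504203, 0.343558, 1.070926, 0.243550, 3.122858, 0.585104, 0.128200, 0.635109, 0.346096, 0.011960)

make_synthetic_fit_problem <- function(resid = c(0, 0, 0)) {
  # patient whose tapping equals the model prediction minus `resid`,
  # so the cost function value is known in closed form
  pk <- pk_parameters(k12 = 1.2, k21 = 1.1, ketot = 2.4)
  pd <- pd_parameters(ke3 = 0.05, T = 10, D0 = 0.5, Dmax = 1.2, Dc50 = 0.5,
                      ND = 4)
  curve <- the_curve()
  tt <- c(30, 60, 120)[seq_along(resid)]
  fmod <- curve_interp(curve, dopaminergic_series(pk, pd, times = tt)$D)
  patient <- list(tapping = tibble::tibble(time_min = tt,
                                           taps_per_min = fmod - resid))
  list(pk = pk, pd = pd, curve = curve, patient = patient)
}

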