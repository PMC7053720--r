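test_that("a zero dose yields identically zero plasma concentration", {
  pk <- pk_parameters()
  out <- simulate_plasma(pk, dose_event(0), times = clinical_times)
  expect_equal(out$conc_mg_l, rep(0, length(clinical_times)))
})

test_that("total drug mass is conserved along the trajectory", {
  set.seed(11)
  for (i in 1:20) {
    pk <- random_pk()
    out <- simulate_plasma(pk, dose_event(100), times = seq(0, 300, by = 15),
                           full = TRUE)
    total <- out$depot_mg + pk$V1 * out$conc_mg_l +
      pk$V2 * out$conc_peripheral_mg_l + out$eliminated_mg
    expect_lt(max(abs(total - 100)) / 100, 1e-6)
  }
})

test_that("the ODE solution matches the closed-form tri-exponential solution", {
  set.seed(21)
  tt <- seq(0, 300, by = 10)
  for (i in 1:100) {
    pk <- random_pk()
    ode <- simulate_plasma(pk, dose_event(100), tt)$conc_mg_l
    ana <- plasma_closed_form(pk, dose_event(100), tt)$conc_mg_l
    expect_lt(max(abs(ode[-1] - ana[-1]) / pmax(ana[-1], 1e-12)), 1e-6)
  }
})

test_that("plasma concentration is linear in the administered dose", {
  pk <- pk_parameters(k12 = 1.1, k21 = 0.8, ketot = 2.6)
  tt <- seq(0, 240, by = 10)
  c100 <- plasma_closed_form(pk, dose_event(100), tt)$conc_mg_l
  c200 <- plasma_closed_form(pk, dose_event(200), tt)$conc_mg_l
  expect_equal(c200, 2 * c100, tolerance = 1e-12)
})

test_that("fit_pk recovers the generating parameters from noise-free data", {
  set.seed(31)
  for (i in 1:20) {
    truth <- random_pk()
    obs <- plasma_closed_form(truth, times = clinical_times)[, c("time_min", "conc_mg_l")]
    fit <- fit_pk(obs)
    est <- fit$parameters
    rel <- abs(c(est$k12, est$k21, est$ketot) -
                 c(truth$k12, truth$k21, truth$ketot)) /
      c(truth$k12, truth$k21, truth$ketot)
    expect_lt(max(rel), 0.05)
  }
})

test_that("fit_pk is already optimal when the data come from the initial guess", {
  truth <- pk_parameters(k12 = 1.5, k21 = 1.5, ketot = 3)
  obs <- plasma_closed_form(truth, times = clinical_times)[, c("time_min", "conc_mg_l")]
  fit <- fit_pk(obs, init = c(1.5, 1.5, 3))
  expect_lt(fit$sse, 1e-8)
})

test_that("fit_pk is deterministic", {
  truth <- pk_parameters(k12 = 0.9, k21 = 1.8, ketot = 2.1)
  obs <- plasma_closed_form(truth, times = clinical_times)[, c("time_min", "conc_mg_l")]
  f1 <- fit_pk(obs)
  f2 <- fit_pk(obs)
  expect_identical(tidy(f1)$estimate, tidy(f2)$estimate)
  expect_identical(f1$sse, f2$sse)
})

test_that("invalid kinetic inputs are rejected with informative conditions", {
  expect_error(pk_parameters(k12 = -1), class = "levotap_invalid_parameter")
  expect_error(simulate_plasma(pk_parameters(), dose_event(), c(0, 10, 10)),
               class = "levotap_input_error")
  obs3 <- tibble::tibble(time_min = c(0, 15, 30), conc_mg_l = c(0, 1, 0.5))
  expect_error(fit_pk(obs3), class = "levotap_input_error")
  obs0 <- tibble::tibble(time_min = clinical_times,
                         conc_mg_l = rep(0, length(clinical_times)))
  expect_error(fit_pk(obs0), class = "levotap_degenerate_data")
})
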