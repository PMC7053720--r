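test_that("parameter draws are seeded, interval-disjoint and correctly ordered", {
  a1 <- sample_parameters(archetype("stable"), seed = 5)
  a2 <- sample_parameters(archetype("stable"), seed = 5)
  expect_identical(a1, a2)
  ke3_s <- vapply(1:50, function(s)
    sample_parameters(archetype("stable"), s)$pd$ke3, numeric(1))
  ke3_f <- vapply(1:50, function(s)
    sample_parameters(archetype("fluctuating"), s)$pd$ke3, numeric(1))
  expect_lt(max(ke3_s), min(ke3_f))
  nd_s <- vapply(1:50, function(s)
    sample_parameters(archetype("stable"), s)$pd$ND, numeric(1))
  nd_f <- vapply(1:50, function(s)
    sample_parameters(archetype("fluctuating"), s)$pd$ND, numeric(1))
  expect_gt(median(nd_f), median(nd_s))
})

test_that("noise-free patients lie exactly on the forward-model curves", {
  p <- generate_patient(archetype("stable", plasma_cv = 0, tapping_sd = 0),
                        seed = 9)
  truth <- p$ground_truth
  c1 <- plasma_closed_form(truth$pk, p$dose, p$plasma$time_min)$conc_mg_l
  expect_equal(p$plasma$conc_mg_l, c1, tolerance = 1e-12)
  fmod <- frequency_from_D_series(the_curve(),
    dopaminergic_series(truth$pk, truth$pd, p$dose, p$tapping$time_min))
  expect_equal(p$tapping$taps_per_min, fmod$taps_per_min, tolerance = 1e-12)
})

test_that("patients follow the clinical sampling schedule", {
  p <- generate_patient(archetype("fluctuating"), seed = 4)
  expect_identical(p$plasma$time_min,
                   c(0, 15, 30, 45, 60, 75, 90, 120, 150, 180))
  expect_equal(nrow(p$plasma), 10)
  expect_equal(range(p$tapping$time_min), c(0, 240))
  expect_true(all(p$plasma$conc_mg_l >= 0) && all(p$tapping$taps_per_min >= 0))
})

test_that("cohorts are reproducible with unique per-patient ground truths", {
  c1 <- generate_cohort(13, 13, master_seed = 7)
  c2 <- generate_cohort(13, 13, master_seed = 7)
  expect_length(c1, 26)
  expect_equal(sum(vapply(c1, `[[`, "", "group") == "stable"), 13)
  expect_identical(c1[[5]]$tapping, c2[[5]]$tapping)
  ke3s <- vapply(c1, function(p) p$ground_truth$pd$ke3, numeric(1))
  expect_equal(anyDuplicated(ke3s), 0)
  expect_equal(anyDuplicated(vapply(c1, `[[`, "", "id")), 0)
  expect_error(generate_cohort(0, 13), class = "levotap_input_error")
})

test_that("archetypes map onto their clinical phenotypes in the majority of draws", {
  # the classifier recovers the intended phenotype for most noise-free
  # draws of each archetype, and fluctuating draws return to baseline far
  # more often than stable draws do
  cls <- function(lab) vapply(1:30, function(s)
    quiet_classify(generate_patient(archetype(lab, 0, 0), seed = s)$tapping),
    character(1))
  stab <- cls("stable")
  fluc <- cls("fluctuating")
  expect_gt(mean(stab == "stable"), 0.5)
  expect_gt(mean(fluc == "fluctuating"), 0.5)
  expect_gt(mean(fluc == "fluctuating"), mean(stab == "fluctuating") + 0.2)
})

test_that("a zero-noise patient is fitted with near-zero cost", {
  p0 <- generate_patient(archetype("stable", 0, 0), seed = 1)
  pn <- generate_patient(archetype("stable"), seed = 1)
  curve <- the_curve()
  f0 <- fit_pd(p0, fit_pk(p0$plasma), curve, seed = 1)
  fn <- fit_pd(pn, fit_pk(pn$plasma), curve, seed = 1)
  expect_lt(f0$cost, 0.005 * fn$cost)
})
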