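test_that("latency to onset uses an inclusive 15 percent threshold", {
  tap <- tibble::tibble(time_min = c(0, 15, 30, 45),
                        taps_per_min = c(100, 110, 115, 130))
  expect_equal(latency_to_onset(tap, 100), 30)
  never <- tibble::tibble(time_min = c(0, 30, 60),
                          taps_per_min = c(100, 114.9, 112))
  expect_true(is.na(latency_to_onset(never, 100)))
  expect_error(latency_to_onset(tap, 0), class = "levotap_input_error")
})

test_that("effect duration is the onset-to-return interval, censored when absent", {
  tap <- tibble::tibble(time_min = c(0, 30, 60, 120, 180, 240),
                        taps_per_min = c(100, 130, 140, 135, 110, 105))
  expect_equal(effect_duration(tap, 100), 180 - 30)
  censored <- tibble::tibble(time_min = c(0, 30, 240),
                             taps_per_min = c(100, 130, 128))
  expect_true(is.na(effect_duration(censored, 100)))
  flat <- tibble::tibble(time_min = c(0, 240), taps_per_min = c(100, 101))
  expect_error(effect_duration(flat, 100), class = "levotap_undefined_duration")
})

test_that("classification separates returners from sustained responders", {
  ret <- tibble::tibble(time_min = c(0, 30, 60, 180, 240),
                        taps_per_min = c(100, 140, 150, 105, 100))
  expect_equal(quiet_classify(ret), "fluctuating")
  sus <- tibble::tibble(time_min = c(0, 30, 240),
                        taps_per_min = c(100, 150, 140))
  expect_equal(quiet_classify(sus), "stable")
  flat <- tibble::tibble(time_min = c(0, 120, 240),
                         taps_per_min = c(100, 104, 101))
  expect_warning(cls <- classify_response(flat), class = "levotap_no_onset_warning")
  expect_equal(as.character(cls), "stable")
  expect_true(attr(cls, "no_onset"))
  m <- response_metrics(ret)
  expect_equal(m$latency_min, 30)
  expect_equal(m$duration_min, 150)
})

test_that("latency and duration are stable under grid refinement of a linear curve", {
  t1 <- seq(0, 240, by = 30)
  shape <- function(t) 100 + 60 * pmax(0, pmin(t / 60, 1)) -
    60 * pmax(0, pmin((t - 120) / 60, 1))
  coarse <- tibble::tibble(time_min = t1, taps_per_min = shape(t1))
  t2 <- seq(0, 240, by = 10)
  fine <- tibble::tibble(time_min = t2, taps_per_min = shape(t2))
  expect_lte(abs(latency_to_onset(coarse, 100) - latency_to_onset(fine, 100)), 30)
  expect_lte(abs(effect_duration(coarse, 100) - effect_duration(fine, 100)), 30)
})

test_that("the exact rank-sum comparison reproduces its combinatorial landmarks", {
  same <- tibble::tibble(p = c(1, 2, 5, 9, 3))
  out <- compare_groups(same, same, parameters = "p")
  expect_equal(out$p_raw, 1)
  g1 <- tibble::tibble(v = as.numeric(1:13))
  g2 <- tibble::tibble(v = as.numeric(14:26))
  sep <- compare_groups(g1, g2, parameters = "v")
  expect_equal(sep$p_raw, 2 / choose(26, 13), tolerance = 1e-10)
  expect_equal(sep$p_bonferroni, min(1, 9 * sep$p_raw))
  # symmetry in group order
  swapped <- compare_groups(g2, g1, parameters = "v")
  expect_equal(swapped$p_raw, sep$p_raw)
  expect_error(compare_groups(g1[1:2, , drop = FALSE], g2),
               class = "levotap_input_error")
})

test_that("the omnibus K2 statistic matches an independent reference", {
  # frozen expected values computed with an independent implementation
  # of the D'Agostino-Pearson test on the fixed helper samples
  gx <- gaussianity_check(normal_fixture())
  expect_equal(gx$statistic, 1.5728901393, tolerance = 1e-8)
  expect_equal(gx$p_value, 0.4554610531, tolerance = 1e-8)
  gy <- gaussianity_check(exp_fixture())
  expect_equal(gy$statistic, 44.5167606297, tolerance = 1e-8)
  expect_lt(gy$p_value, 1e-9)
  expect_error(gaussianity_check(rnorm(5)), class = "levotap_input_error")
})

test_that("the K2 test keeps its nominal size on normal data and flags strong skew", {
  set.seed(77)
  p_norm <- vapply(1:25, function(i) gaussianity_check(rnorm(500))$p_value,
                   numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.8)
  expect_lt(gaussianity_check(rexp(10000))$p_value, 1e-3)
})
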