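test_that("an isolated unit relaxes exponentially with the neuron time constant", {
  # zero all couplings so every unit is an independent first-order filter
  cfg <- bg_config(wL = 0, wThM = 0, wMTh = 0, gGo = 0, gNoGo = 0,
                   wGoGPi = 0, wNoGoGPe = 0, wGPeGPi = 0, wGPiTh = 0,
                   wChNoGo = 0, tonicGPe = 0, tonicGPi = 0, tonicCh = 0,
                   alphaGo = 0, betaNoGo = 0, kChD = 0)
  syn <- synapse_set()
  tr <- run_network(rep(0, 13), cfg, syn, stimulus = c(0, 0), D = 0,
                    duration_ms = 5 * cfg$tau_ms, record_every_ms = 1)
  sig0 <- 1 / (1 + exp(cfg$sig_a * cfg$sig_u0))  # sigma(0)
  expected <- sig0 * (1 - exp(-tr$time_ms / cfg$tau_ms))
  expect_lt(max(abs(tr$M1 - expected)), 1e-3)
  expect_lt(abs(tail(tr$M1, 1) - sig0 * (1 - exp(-5))), 1e-3)
})

test_that("halving the integration step barely changes the trajectory", {
  cfg1 <- default_bg_config()
  cfg2 <- bg_config(dt_ms = 0.05)
  syn <- default_synapses()
  s0 <- rep(0, 13)
  a <- run_network(s0, cfg1, syn, stimulus = c(cfg1$stim_amp, 0), D = 1.5,
                   duration_ms = 500, record_every_ms = 5)
  b <- run_network(s0, cfg2, syn, stimulus = c(cfg1$stim_amp, 0), D = 1.5,
                   duration_ms = 500, record_every_ms = 5)
  expect_lt(max(abs(as.matrix(a[-1]) - as.matrix(b[-1]))), 1e-3)
})

test_that("dopamine suppresses the cholinergic unit", {
  cfg <- default_bg_config()
  syn <- default_synapses()
  ch0 <- bg_rest_state(cfg, syn, D = 0)[["Ch"]]
  ch5 <- bg_rest_state(cfg, syn, D = 5)[["Ch"]]
  expect_lt(ch5, ch0)
})

test_that("unit activities stay inside the sigmoid codomain for random drives", {
  set.seed(41)
  syn <- synapse_set()
  for (i in 1:10) {
    cfg <- bg_config(alphaGo = runif(1, 0, 2), betaNoGo = runif(1, 0, 2),
                     tonicGPi = runif(1, 0, 4), tonicGPe = runif(1, 0, 4),
                     tonicCh = runif(1, 0, 4), stim_amp = runif(1, 0, 3))
    tr <- run_network(runif(13), cfg, syn, stimulus = rnorm(2, 0, 2),
                      D = runif(1, 0, 5), duration_ms = 200,
                      record_every_ms = 10)
    vals <- as.matrix(tr[-1])
    expect_true(all(vals >= -1e-9 & vals <= 1 + 1e-9))
  }
})

test_that("step_network agrees with the long-run integrator", {
  cfg <- default_bg_config()
  syn <- default_synapses()
  s <- rep(0.2, 13)
  names(s) <- names(bg_rest_state(cfg, syn))
  one <- step_network(s, cfg, syn, stimulus = c(1, 0), D = 1)
  tr <- run_network(s, cfg, syn, stimulus = c(1, 0), D = 1,
                    duration_ms = cfg$dt_ms, record_every_ms = cfg$dt_ms)
  expect_equal(unname(one), as.numeric(tr[nrow(tr), -1]), tolerance = 1e-12)
})

test_that("dopamine silences NoGo and supports the winning Go channel", {
  cfg <- default_bg_config()
  syn <- default_synapses()
  p <- levotap:::bg_param_vector(cfg)
  act <- function(D) {
    rest <- bg_rest_state(cfg, syn, D = D)
    tr <- run_network(rest, cfg, syn, stimulus = c(cfg$stim_amp, 0), D = D,
                      duration_ms = 600, record_every_ms = 600)
    unlist(tr[nrow(tr), c("N1", "G1")])
  }
  a <- vapply(c(0, 0.5, 1, 2, 4), act, numeric(2))
  expect_true(all(diff(a["N1", ]) < 0))
  expect_true(all(diff(a["G1", ]) > -0.02))
})

test_that("selection latency shrinks as dopaminergic input rises", {
  cfg <- default_bg_config()
  syn <- default_synapses()
  p <- levotap:::bg_param_vector(cfg)
  lat <- vapply(seq(0.4, 3, length.out = 10), function(D) {
    rest <- bg_rest_state(cfg, syn, D = D)
    .bg_select_cpp <- levotap:::`.bg_select_cpp`
    levotap:::.bg_select_cpp(p, rest, syn$wGo, syn$wNoGo, 0L, c(0, 0),
                             D)$latency_ms
  }, numeric(1))
  expect_true(all(diff(lat) <= 1e-9))
})

test_that("tapping trials are deterministic and bounded by the movement lag", {
  cfg <- default_bg_config()
  syn <- default_synapses()
  t1 <- simulate_tapping_trial(cfg, syn, D = 2, n_cycles = 10)
  t2 <- simulate_tapping_trial(cfg, syn, D = 2, n_cycles = 10)
  expect_identical(t1$tap_times_ms, t2$tap_times_ms)
  expect_lte(t1$taps_per_min, 60000 / cfg$lag_ms)
})

test_that("the frequency curve is monotone with a saturated plateau and bradykinetic floor", {
  curve <- the_curve()
  expect_true(all(diff(curve$taps_per_min) >= -1e-6))
  n <- nrow(curve)
  expect_lt(abs(curve$taps_per_min[n] - curve$taps_per_min[n - 1]) /
              curve$taps_per_min[n], 0.01)
  expect_lte(curve$taps_per_min[1], 100)
})

test_that("frequency_from_D_series interpolates, clamps and preserves monotonicity", {
  curve <- the_curve()
  node <- tibble::tibble(time_min = c(0, 10, 20), D = rep(curve$D[5], 3))
  out <- frequency_from_D_series(curve, node)
  expect_equal(out$taps_per_min, rep(curve$taps_per_min[5], 3))
  below <- frequency_from_D_series(curve,
    tibble::tibble(time_min = 0:1, D = c(-3, -1)))
  expect_equal(below$taps_per_min, rep(curve$taps_per_min[1], 2))
  mono <- frequency_from_D_series(curve,
    tibble::tibble(time_min = 0:10, D = seq(0, 5, length.out = 11)))
  expect_true(all(diff(mono$taps_per_min) >= -1e-9))
})

test_that("invert_frequency is a clamped inverse of the curve", {
  curve <- the_curve()
  for (i in c(4, 10, 16)) {
    Dstar <- curve$D[i]
    expect_lt(abs(invert_frequency(curve, curve$taps_per_min[i]) - Dstar),
              diff(curve$D[1:2]) + 1e-9)
  }
  expect_equal(invert_frequency(curve, 1e4), curve$D[which.max(curve$taps_per_min)])
  expect_equal(invert_frequency(curve, 0), curve$D[1])
})

test_that("the shipped configuration passes the calibration constraints", {
  cfg <- calibrate_network(default_bg_config(), default_synapses())
  checks <- attr(cfg, "checks")
  expect_true(all(checks$ok))
  expect_identical(unclass(cfg)[names(unclass(default_bg_config()))],
                   unclass(default_bg_config()))
})

test_that("the calibration constraints actually bind", {
  cfg <- default_bg_config()
  cfg$alphaGo <- cfg$alphaGo * 0.3
  checks <- levotap:::check_calibration(cfg, default_synapses(),
                                        bg_calibration_constraints())
  expect_true(any(!checks$ok))
})

test_that("an empty constraint list leaves the configuration untouched", {
  cfg <- bg_config(alphaGo = 0.01)  # would fail every anchor
  expect_identical(calibrate_network(cfg, synapse_set(), list()), cfg)
})
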