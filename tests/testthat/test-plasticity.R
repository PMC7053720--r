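test_that("the threshold Hebb rule matches its closed-form values", {
  expect_equal(hebbian_update(0.8, 0.9, gamma = 0.1, theta = 0.5), 0.032)
  expect_equal(hebbian_update(0.7, 0.5, gamma = 0.1, theta = 0.5), 0)
  expect_equal(hebbian_update(0, 0.99, gamma = 0.1, theta = 0.5), 0)
  # depression below threshold
  expect_lt(hebbian_update(0.5, 0.2, gamma = 0.1, theta = 0.5), 0)
})

test_that("a zero learning rate leaves weights unchanged but logs every epoch", {
  cfg <- default_bg_config()
  syn <- synapse_set(c(0.6, 0.7), c(0.4, 0.5))
  sess <- run_training_session(cfg, syn,
                               training_protocol(n_epochs = 50, gamma = 0,
                                                 seed = 7), D = 1.5)
  expect_equal(sess$synapses$wGo, syn$wGo)
  expect_equal(sess$synapses$wNoGo, syn$wNoGo)
  expect_equal(nrow(sess$log), 50)
})

test_that("training sessions are reproducible under a fixed seed", {
  cfg <- default_bg_config()
  syn <- synapse_set()
  a <- run_training_session(cfg, syn, training_protocol(n_epochs = 15, seed = 3),
                            D = 1.5)
  b <- run_training_session(cfg, syn, training_protocol(n_epochs = 15, seed = 3),
                            D = 1.5)
  expect_identical(a$log, b$log)
  expect_identical(a$synapses, b$synapses)
})

test_that("with noiseless cues at high dopamine every trial is rewarded and Go grows", {
  cfg <- default_bg_config()
  syn <- synapse_set()
  sess <- run_training_session(cfg, syn,
    training_protocol(n_epochs = 20, noise_sd = 0, seed = 5), D = 2.5)
  expect_true(all(sess$log$outcome == "reward"))
  w <- as.matrix(sess$log[, c("wGo1", "wGo2")])
  expect_true(all(diff(w[, 1]) >= -1e-12 & diff(w[, 2]) >= -1e-12))
})

test_that("weights remain inside [0, wmax] after training", {
  cfg <- default_bg_config()
  sess <- run_training_session(cfg, synapse_set(c(1.45, 1.45), c(0.05, 0.05)),
    training_protocol(n_epochs = 40, gamma = 0.3, seed = 9), D = 1.5)
  w <- c(sess$synapses$wGo, sess$synapses$wNoGo)
  expect_true(all(w >= 0 & w <= sess$synapses$wmax))
})

test_that("synapse presets are deterministic and ordered by skill", {
  s1 <- synapse_presets(100)
  s2 <- synapse_presets(100)
  expect_identical(s1, s2)
  cfg <- default_bg_config()
  f60 <- simulate_tapping_trial(cfg, synapse_presets(60), D = 1)$taps_per_min
  f200 <- simulate_tapping_trial(cfg, synapse_presets(200), D = 1)$taps_per_min
  expect_gte(f200, f60)
  expect_error(synapse_presets(0), class = "levotap_input_error")
})

test_that("late-dose training grows NoGo more than Go while early training favours Go", {
  # the mechanistic core of aberrant learning: at a low dopaminergic input
  # most trials are punished (D nulled, NoGo active above the Hebb
  # threshold) and the rare rewards only double an already small D
  cfg <- default_bg_config()
  syn <- default_synapses()
  d_go_low <- d_nogo_low <- d_go_high <- d_nogo_high <- numeric(0)
  for (s in 1:5) {
    lo <- run_training_session(cfg, syn,
      training_protocol(n_epochs = 30, seed = s), D = 0.35)
    hi <- run_training_session(cfg, syn,
      training_protocol(n_epochs = 30, seed = s), D = 2.5)
    d_go_low <- c(d_go_low, mean(lo$synapses$wGo - syn$wGo))
    d_nogo_low <- c(d_nogo_low, mean(lo$synapses$wNoGo - syn$wNoGo))
    d_go_high <- c(d_go_high, mean(hi$synapses$wGo - syn$wGo))
    d_nogo_high <- c(d_nogo_high, mean(hi$synapses$wNoGo - syn$wNoGo))
  }
  expect_gt(mean(d_nogo_low), mean(d_go_low))
  expect_gt(mean(d_go_high), 0)
  expect_gt(mean(d_go_high), mean(d_go_low))
})

test_that("a null experiment reproduces the untrained trajectory exactly", {
  p <- generate_patient(archetype("fluctuating", 0, 0), seed = 2)
  tr <- p$ground_truth
  e <- simulate_training_experiment(tr$pk, tr$pd,
    training_protocol(gamma = 0, seed = 1, session_time_min = 210))
  expect_equal(e$trained, e$untrained)
})
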