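test_that("the cost function reproduces its worked residual cases", {
  z <- make_synthetic_fit_problem(c(0, 0, 0))
  expect_equal(pd_cost(z$pd, z$patient, z$pk, z$curve), 0, tolerance = 1e-9)
  a <- make_synthetic_fit_problem(c(1, 1, 1))
  expect_equal(pd_cost(a$pd, a$patient, a$pk, a$curve), 3 + 10 * 1,
               tolerance = 1e-8)
  b <- make_synthetic_fit_problem(c(0, 0, 2))
  expect_equal(pd_cost(b$pd, b$patient, b$pk, b$curve), 4 + 10 * 2,
               tolerance = 1e-8)
})

test_that("the cost is invariant to the order of the measurement points", {
  z <- make_synthetic_fit_problem(c(2, -1, 0.5))
  tap <- z$patient$tapping
  perm <- tap[c(2, 3, 1), ]
  # re-sort so the series is valid but originated from a permuted set
  perm <- perm[order(perm$time_min), ]
  p2 <- list(tapping = perm)
  expect_equal(pd_cost(z$pd, z$patient, z$pk, z$curve),
               pd_cost(z$pd, p2, z$pk, z$curve))
})

test_that("the compiled cost evaluation matches the reference R pipeline", {
  p <- generate_patient(archetype("stable"), seed = 5)
  pk <- p$ground_truth$pk
  curve <- the_curve()
  obj <- levotap:::make_pd_objective(p, pk, curve, grid_min = 1)
  for (th in list(c(0.02, 10.3, 0.5, 1, 0.5, 3),
                  c(0.1, 0, 0.3, 2, 0.4, 9))) {
    pd <- pd_parameters(ke3 = th[1], T = th[2], D0 = th[3], Dmax = th[4],
                        Dc50 = th[5], ND = th[6])
    expect_equal(obj(th), pd_cost(pd, p, pk, curve), tolerance = 1e-9)
  }
})

test_that("compute_r2 reproduces its worked cases and contracts", {
  expect_equal(compute_r2(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(1, 2, 3, 6)
  expect_equal(compute_r2(rep(mean(obs), 4), obs), 0)
  expect_equal(compute_r2(c(1, 2, 4), c(1, 2, 3)), 0.5)
  expect_error(compute_r2(c(1, 2), c(1, 2, 3)), class = "levotap_input_error")
  expect_error(compute_r2(c(1, 2), c(2, 2)), class = "levotap_degenerate_data")
})

test_that("fit_pd is reproducible and improves monotonically with restarts", {
  p <- generate_patient(archetype("fluctuating"), seed = 8)
  pkf <- fit_pk(p$plasma)
  curve <- the_curve()
  f1 <- fit_pd(p, pkf, curve, n_restarts = 10, seed = 4)
  f2 <- fit_pd(p, pkf, curve, n_restarts = 10, seed = 4)
  expect_identical(f1$cost, f2$cost)
  expect_identical(tidy(f1)$estimate, tidy(f2)$estimate)
  costs <- vapply(c(1, 5, 10), function(n)
    fit_pd(p, pkf, curve, n_restarts = n, seed = 4)$cost, numeric(1))
  expect_true(all(diff(costs) <= 1e-9))
})

test_that("a missing pre-dose tapping sample falls back to the earliest sample", {
  p <- generate_patient(archetype("stable"), seed = 3)
  p$tapping <- p$tapping[p$tapping$time_min > 0, ]
  pkf <- fit_pk(p$plasma)
  expect_warning(fit_pd(p, pkf, the_curve(), n_restarts = 2, seed = 1),
                 "baseline")
})

test_that("noise-free fits separate the archetypes in the (ke3, ND) plane", {
  curve <- the_curve()
  est <- function(lab, s) {
    p <- generate_patient(archetype(lab, 0, 0), seed = s)
    f <- fit_pd(p, fit_pk(p$plasma), curve, seed = 300 + s)
    c(f$parameters$ke3, f$parameters$ND)
  }
  stab <- vapply(1:5, function(s) est("stable", s), numeric(2))
  fluc <- vapply(1:5, function(s) est("fluctuating", s), numeric(2))
  expect_lt(max(stab[1, ]), min(fluc[1, ]))  # ke3: disjoint
  expect_lt(max(stab[2, ]), min(fluc[2, ]))  # ND: disjoint
})

test_that("synapse sensitivity is an identity at the reference level", {
  p <- generate_patient(archetype("stable", 0, 0), seed = 1)
  tr <- p$ground_truth
  tab <- synapse_sensitivity_analysis(tr$pk, tr$pd, levels = c(100),
                                      times = seq(0, 240, by = 20))
  expect_equal(tab$sup_dev, 0)
  expect_equal(tab$D0, tr$pd$D0, tolerance = 0.05)
})
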