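# Stochastic lung deposition: mechanism formulas, APSD sampling, and the
# Monte Carlo walk with breath hold and exhalation.

test_that("extrathoracic efficiency has the right limits and monotonicity", {
  expect_gt(extrathoracic_efficiency(100, 31.9), 0.99)
  expect_lt(extrathoracic_efficiency(0.01, 31.9), 1e-4)
  for (q in c(15, 30, 60)) {
    expect_gt(extrathoracic_efficiency(7, q), extrathoracic_efficiency(3, q))
  }
  d <- seq(0.5, 20, by = 0.5)
  eta <- extrathoracic_efficiency(d, 31.9)
  expect_true(all(diff(eta) > 0))
  expect_true(all(eta >= 0 & eta <= 1))
  expect_error(extrathoracic_efficiency(-1, 30), "positive")
})

test_that("tube deposition probability behaves mechanistically", {
  # zero flow and zero residence: nothing deposits
  p0 <- generation_deposition_prob(3, diam_cm = 0.3, velocity_cm_s = 0,
                                   residence_s = 0)
  expect_equal(p0$p, 0)

  # sedimentation increases with residence time at zero flow
  t_grid <- c(0.5, 1, 2, 5, 10)
  es <- vapply(t_grid, function(t) {
    generation_deposition_prob(3, 0.3, 0, t, gravity_angle_deg = 45)$eta_sed
  }, numeric(1))
  expect_true(all(diff(es) > 0))

  # impaction dominates for coarse particles at bronchial velocities
  p10 <- generation_deposition_prob(10, 0.83, 250, 0.01)$eta_imp
  p1 <- generation_deposition_prob(1, 0.83, 250, 0.01)$eta_imp
  expect_gt(p10, 50 * max(p1, 1e-12))

  # diffusion matters only for fine particles
  d_small <- generation_deposition_prob(0.05, 0.05, 1, 0.5)$eta_diff
  d_big <- generation_deposition_prob(5, 0.05, 1, 0.5)$eta_diff
  expect_gt(d_small, d_big)

  # all mechanism efficiencies are probabilities
  set.seed(31)
  for (i in 1:100) {
    p <- generation_deposition_prob(runif(1, 0.1, 20), runif(1, 0.04, 1.8),
                                    runif(1, 0, 500), runif(1, 0, 5),
                                    gravity_angle_deg = runif(1, 0, 90))
    for (eta in unlist(p)) {
      expect_gte(eta, 0); expect_lte(eta, 1)
    }
  }
})

test_that("airway geometry is a consistent scaled tree", {
  g <- airway_geometry(3300)
  expect_identical(nrow(g), 24L)
  expect_true(all(diff(g$diam_cm) <= 0))
  expect_equal(g$multiplicity, 2^(0:23))
  expect_equal(g$cum_volume_ml[24], 3300, tolerance = 1e-9)
  # isometric scaling of linear dimensions
  g2 <- airway_geometry(4800)
  expect_equal(g2$length_cm / g$length_cm,
               rep((4800 / 3300)^(1 / 3), 24), tolerance = 1e-12)
})

test_that("APSD sampling is mass-weighted lognormal with a seed contract", {
  d <- sample_apsd(3.41, 1.0001, n = 1e4, seed = 1)
  expect_true(all(abs(d - 3.41) < 0.01))

  d <- sample_apsd(3.41, 1.8, n = 1e5, seed = 2)
  expect_lt(abs(exp(mean(log(d))) / 3.41 - 1), 0.01)
  expect_lt(abs(exp(sd(log(d))) / 1.8 - 1), 0.02)

  a <- sample_apsd(3.41, 1.8, 1000, seed = 3)
  b <- sample_apsd(3.41, 1.8, 1000, seed = 4)
  expect_false(identical(a, b))
  expect_lt(abs(median(a) - median(b)) / 3.41, 0.1)
  expect_identical(a, sample_apsd(3.41, 1.8, 1000, seed = 3))
  expect_error(sample_apsd(3.41, 0.9, 10), "gsd")
})

test_that("deposition fractions conserve mass exactly", {
  for (seed in 1:5) {
    res <- simulate_deposition(3.41, 1.8, copd_profile(5), n = 2000,
                               seed = seed)
    expect_equal(res$et_pct + res$lung_pct + res$exh_pct, 100,
                 tolerance = 1e-9)
    expect_equal(sum(res$per_generation_pct), res$lung_pct,
                 tolerance = 1e-9)
    expect_equal(res$bronchial_pct + res$acinar_pct, res$lung_pct,
                 tolerance = 1e-12)
  }
})

test_that("very coarse particles deposit extrathoracically", {
  res <- simulate_deposition(profile = copd_profile(5), n = 2000, seed = 1,
                             diameters_um = rep(100, 2000))
  expect_gt(res$et_pct, 99)
})

test_that("breath hold shifts exhaled mass into the lung (paired seeds)", {
  for (seed in c(11, 12)) {
    r0 <- simulate_deposition(3.41, 1.8, copd_profile(0), n = 2e4,
                              seed = seed)
    r5 <- simulate_deposition(3.41, 1.8, copd_profile(5), n = 2e4,
                              seed = seed)
    r10 <- simulate_deposition(3.41, 1.8, copd_profile(10), n = 2e4,
                               seed = seed)
    expect_lte(r5$exh_pct, r0$exh_pct)
    expect_lte(r10$exh_pct, r5$exh_pct)
    expect_gte(r5$lung_pct, r0$lung_pct)
    expect_gte(r10$lung_pct, r5$lung_pct)
    expect_identical(r5$et_pct, r10$et_pct)   # ET unaffected by the hold
  }
})

test_that("ET grows with MMAD; exhaled fraction peaks for fine aerosols", {
  ets <- vapply(c(1, 2, 4, 7, 10), function(m) {
    simulate_deposition(m, 1.8, copd_profile(5), n = 1e4, seed = 5)$et_pct
  }, numeric(1))
  expect_true(all(diff(ets) > -0.5))    # non-decreasing up to MC noise
  exh_fine <- simulate_deposition(0.5, 1.3, copd_profile(0), n = 1e4,
                                  seed = 6)$exh_pct
  exh_coarse <- simulate_deposition(6.5, 1.8, copd_profile(0), n = 1e4,
                                    seed = 6)$exh_pct
  expect_gt(exh_fine, exh_coarse)
})

test_that("Monte Carlo runs are reproducible and stable in n", {
  a <- simulate_deposition(3.41, 1.8, copd_profile(5), n = 5000, seed = 9)
  b <- simulate_deposition(3.41, 1.8, copd_profile(5), n = 5000, seed = 9)
  expect_identical(a, b)

  n1 <- 2e4; n2 <- 4e4
  r1 <- simulate_deposition(3.41, 1.8, copd_profile(5), n = n1, seed = 10)
  r2 <- simulate_deposition(3.41, 1.8, copd_profile(5), n = n2, seed = 11)
  for (field in c("et_pct", "lung_pct", "exh_pct")) {
    p <- r1[[field]] / 100
    se <- 100 * sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
    expect_lt(abs(r1[[field]] - r2[[field]]), 3 * se + 1e-9)
  }
})

test_that("invalid simulator inputs are rejected", {
  expect_error(simulate_deposition(3.41, 1.8, copd_profile(5), n = 50),
               "at least 100")
  expect_error(breathing_profile(-1, 3, 5, 3), "positive")
  expect_error(breathing_profile(1.7, 3.2, -1, 3), "non-negative")
})
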