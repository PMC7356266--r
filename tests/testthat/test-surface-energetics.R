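# Wu inversion and interparticle-interaction metrics.

test_that("Wu inversion reproduces the published reference rows", {
  for (m in names(ref_materials)) {
    ref <- ref_materials[[m]]
    se <- solve_ref_material(m)
    expect_equal(se$gamma_sd, ref$gamma_sd, tolerance = 0.02 / ref$gamma_sd,
                 info = m)
    expect_equal(se$gamma_sp, ref$gamma_sp, tolerance = 0.02 / ref$gamma_sp,
                 info = m)
    expect_equal(se$gamma_s, ref$gamma_s, tolerance = 0.02 / ref$gamma_s,
                 info = m)
    expect_lt(abs(se$polarity_pct - ref$polarity), 0.05)
    expect_lt(abs(se$cohesion_work - ref$wc), 0.04)
  }
})

test_that("solved components back-substitute into both Wu equations", {
  liquids <- default_probe_liquids()
  for (m in names(ref_materials)) {
    se <- solve_ref_material(m)
    for (liq in liquids) {
      lhs <- (1 + cos(ref_materials[[m]]$theta[[liq$name]] * pi / 180)) *
        liq$gamma_total
      rhs <- 4 * se$gamma_sd * liq$gamma_d / (se$gamma_sd + liq$gamma_d) +
        4 * se$gamma_sp * liq$gamma_p / (se$gamma_sp + liq$gamma_p)
      expect_lt(abs(lhs - rhs), 1e-8)
    }
  }
})

test_that("forward angle generation then inversion round-trips components", {
  set.seed(42)
  liquids <- default_probe_liquids()
  n_ok <- 0L
  for (i in 1:3000) {
    if (n_ok >= 1000L) break
    truth <- runif(2, 1, 80)
    th <- tryCatch(
      c(water = forward_contact_angle(truth[1], truth[2], liquids$water),
        diiodomethane = forward_contact_angle(truth[1], truth[2],
                                              liquids$diiodomethane)),
      error = function(e) NULL)  # corners where the Wu adhesion exceeds
    if (is.null(th)) next        # 2*gamma_l have no measurable angle
    se <- solve_wu(contact_angle_set("x", th), liquids)
    expect_equal(c(se$gamma_sd, se$gamma_sp), truth, tolerance = 1e-6)
    n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 1000L)
})

test_that("work of adhesion is symmetric and self-adhesion equals cohesion", {
  a <- solve_ref_material("uMXP"); b <- solve_ref_material("IH70")
  expect_identical(work_of_adhesion(a, b), work_of_adhesion(b, a))
  expect_equal(work_of_adhesion(a, a), cohesion_work(a), tolerance = 1e-12)
  expect_equal(spreading_coefficient(a, a), 0, tolerance = 1e-9)
})

test_that("harmonic-mean adhesion never exceeds the geometric-mean value", {
  set.seed(7)
  g1d <- runif(1e4, 0.1, 80); g1p <- runif(1e4, 0.1, 80)
  g2d <- runif(1e4, 0.1, 80); g2p <- runif(1e4, 0.1, 80)
  harm <- 4 * (g1d * g2d / (g1d + g2d) + g1p * g2p / (g1p + g2p))
  geom <- 2 * (sqrt(g1d * g2d) + sqrt(g1p * g2p))
  expect_true(all(harm <= geom + 1e-12))
  # spot-check the vectorised oracle against the object route
  i <- 123
  expect_equal(
    work_of_adhesion(surface_energy("a", g1d[i], g1p[i]),
                     surface_energy("b", g2d[i], g2p[i])),
    harm[i])
})

test_that("cohesion work doubles the total surface energy", {
  expect_equal(cohesion_work(75.25), 150.50)
  expect_equal(cohesion_work(26.96), 53.92)
  expect_equal(cohesion_work(0), 0)
})

test_that("Derjaguin force reproduces the published pair values", {
  for (nm in c("uMXP + IH70", "MXPspd + IH70")) {
    ref <- ref_pairs[[nm]]
    f <- adhesion_force(ref$w_adh_printed, ref$d50[1], ref$d50[2])
    expect_equal(signif(f, 3), signif(ref$f_adh, 3), info = nm)
  }
  # MgSt-coated rows deviate ~1-2% with the uncoated carrier D(0.5): the
  # coated-carrier diameter is not published. Documented, not asserted.
  for (nm in c("uMXP + IH70_MgSt", "MXPspd + IH70_MgSt")) {
    ref <- ref_pairs[[nm]]
    f <- adhesion_force(ref$w_adh_printed, ref$d50[1], ref$d50[2])
    expect_lt(abs(f / ref$f_adh - 1), 0.03, label = nm)
  }
})

test_that("Derjaguin force: equal spheres closed form and monotonicity", {
  w <- 100; d <- 4
  expect_equal(adhesion_force(w, d, d), pi * d * w / 2 * 1e-6,
               tolerance = 1e-12)  # reduced radius d/4 um
  expect_lt(adhesion_force(50, 3, 200), adhesion_force(60, 3, 200))
  expect_lt(adhesion_force(50, 3, 200), adhesion_force(50, 4, 200))
  expect_lt(adhesion_force(50, 3, 200), adhesion_force(50, 3, 300))
  # reduced radius never exceeds the smaller radius
  expect_lt(adhesion_force(1, 3, 1e9) / (2 * pi), 1.5e-6 * 1.0000001)
})

test_that("spreading coefficients match the published pair values", {
  # the +/-0.01 reproduction is defined on the published (2-decimal)
  # component table; the full solved-angle route agrees to ~0.02
  for (nm in names(ref_pairs)) {
    ref <- ref_pairs[[nm]]
    printed <- function(m) surface_energy(m, ref_materials[[m]]$gamma_sd,
                                          ref_materials[[m]]$gamma_sp)
    s21_tab <- spreading_coefficient(printed(ref$drug), printed(ref$carrier))
    expect_lt(abs(s21_tab - ref$s21), 0.01, label = nm)
    s21_solved <- spreading_coefficient(solve_ref_material(ref$drug),
                                        solve_ref_material(ref$carrier))
    expect_lt(abs(s21_solved - ref$s21), 0.05, label = paste(nm, "(solved)"))
  }
})

test_that("interaction_pair reports both adhesion-work routes", {
  ref <- ref_pairs[["uMXP + IH70"]]
  ip <- interaction_pair(solve_ref_material("uMXP"), solve_ref_material("IH70"),
                         ref$d50[1], ref$d50[2],
                         w_adh_override = ref$w_adh_printed)
  expect_equal(signif(ip$f_adh, 3), signif(ref$f_adh, 3))  # force from override
  expect_gt(ip$w_adh, 150)                          # harmonic-mean route kept
  expect_lt(abs(ip$s21 - ref$s21), 0.01)
})

test_that("invalid inputs fail loudly", {
  expect_error(solve_wu(contact_angle_set("x", c(water = 10)),
                        default_probe_liquids()), "missing contact angle")
  same <- list(probe_liquid("a", 20, 10), probe_liquid("b", 40, 20))
  expect_error(solve_wu(contact_angle_set("x", c(a = 10, b = 20)), same),
               "colinear")
  expect_error(contact_angle_set("x", c(water = -5, diiodomethane = 3)))
  expect_error(probe_liquid("w", -1, 5))
  expect_error(adhesion_force(100, -1, 10), "positive")
  expect_error(adhesion_force(0, 1, 10), "positive")
})
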