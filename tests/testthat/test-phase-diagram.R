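test_that("liquidus_curve hits the pure limits and decreases toward dilution", {
  sys <- walden_600_300()
  c1 <- liquidus_curve(sys, 1, c(0.2, 0.5, 0.8, 1))
  expect_equal(c1$T_K[c1$x1 == 1], 600)
  expect_true(all(diff(c1$T_K) > 0))   # branch 1 falls as x1 decreases
  c2 <- liquidus_curve(sys, 2, c(0, 0.3, 0.6))
  expect_equal(c2$T_K[c2$x1 == 0], 300)
  expect_true(all(diff(c2$T_K) < 0))
  expect_error(liquidus_curve(sys, 1, numeric(0)), class = "slekit_domain_error")
  expect_error(liquidus_curve(sys, 3, 0.5), class = "slekit_domain_error")
  # infeasible compositions are flagged, not dropped
  sysn <- binary_system(melting_properties(600, walden_enthalpy(600)),
                        melting_properties(300, 6000),
                        coeffs2 = rk_coefficients(-30000))
  c2n <- liquidus_curve(sysn, 2, c(0.1, 0.9))
  expect_equal(c2n$feasible, c(TRUE, FALSE))
})

test_that("symmetric systems have an equimolar eutectic", {
  ep <- eutectic_point(symmetric_system())
  expect_equal(ep$x1_e, 0.5, tolerance = 1e-9)
  expect_lt(ep$Te, 400)
  expect_equal(ep$gamma1_e, 1)
  # symmetric non-ideality preserves the 1:1 ratio
  eps <- eutectic_point(binary_system(
    melting_properties(400, 20000), melting_properties(400, 20000),
    rk_coefficients(-10000), rk_coefficients(-10000)))
  expect_equal(eps$x1_e, 0.5, tolerance = 1e-9)
  expect_lt(eps$Te, ep$Te)
})

test_that("eutectic point matches the dense-grid upper-envelope oracle", {
  # ideal dissimilar pair: eutectic sits very close to the pure low-melting side
  ep <- eutectic_point(walden_600_300())
  or <- oracle_eutectic(600, 32640, 300, 16320)
  expect_lt(ep$x1_e, 0.01)
  expect_lt(ep$Te, 300)
  expect_gt(ep$Te, 295)
  expect_lt(abs(ep$x1_e - or$x1_e), or$dx * 2)
  expect_lt(abs(ep$Te - or$Te), 1e-3)
  # strong Component-1 non-ideality deepens the eutectic and pushes it to
  # higher Component-1 content
  epn <- eutectic_point(walden_600_300(a1 = -30000))
  orn <- oracle_eutectic(600, 32640, 300, 16320, a1 = -30000)
  expect_lt(epn$Te, ep$Te)
  expect_gt(epn$x1_e, ep$x1_e)
  expect_lt(abs(epn$x1_e - orn$x1_e), orn$dx * 2)
  expect_lt(abs(epn$Te - orn$Te), 1e-3)
  # activity coefficients at the eutectic come from each branch's polynomial
  expect_equal(log(epn$gamma1_e), -30000 * (1 - epn$x1_e)^2 / (R_GAS * epn$Te),
               tolerance = 1e-12)
  expect_equal(epn$gamma2_e, 1)
})

test_that("eutectic solver reports a typed error when branches never coexist", {
  # over-strong negative deviation on both branches leaves no composition
  # where both liquidus lines are physical, so no intersection can exist
  sys <- binary_system(melting_properties(600, 3000), melting_properties(300, 1000),
                       rk_coefficients(-30000), rk_coefficients(-30000))
  expect_error(eutectic_point(sys), class = "slekit_no_eutectic_error")
})

test_that("normalized depression is the dimensionless distance below the reference", {
  expect_identical(normalized_depression(300, 300), 0)
  expect_equal(normalized_depression(270, 300), 0.1)
  expect_error(normalized_depression(270, -1), class = "slekit_domain_error")
})

test_that("fixed melting entropies make the eutectic scale-invariant", {
  base <- eutectic_point(walden_600_300())
  for (lam in c(0.1, 10)) {
    sys <- binary_system(
      melting_properties(600 * lam, walden_enthalpy(600 * lam)),
      melting_properties(300 * lam, walden_enthalpy(300 * lam)))
    ep <- eutectic_point(sys)
    expect_equal(ep$x1_e, base$x1_e, tolerance = 1e-9)
    expect_equal(ep$Te, base$Te * lam, tolerance = 1e-9)
    expect_equal(ep$norm_depression, base$norm_depression, tolerance = 1e-9)
  }
})

test_that("at fixed entropies the depression peaks where the melting temperatures meet", {
  ratios <- seq(1, 3, by = 0.25)
  dep <- vapply(ratios, function(r) {
    sys <- binary_system(
      melting_properties(300 * r, walden_enthalpy(300 * r)),
      melting_properties(300, walden_enthalpy(300)))
    eutectic_point(sys)$norm_depression
  }, numeric(1))
  expect_equal(which.max(dep), 1L)       # Tm1 = Tm2
  expect_true(all(diff(dep) < 0))        # monotone fall as the gap widens
})

test_that("lowering either branch coefficient never raises the eutectic temperature", {
  a_grid <- seq(0, -30000, by = -10000)
  Te_a1 <- vapply(a_grid, function(a)
    eutectic_point(walden_600_300(a1 = a))$Te, numeric(1))
  Te_a2 <- vapply(a_grid, function(a)
    eutectic_point(walden_600_300(a2 = a))$Te, numeric(1))
  expect_true(all(diff(Te_a1) <= 1e-9))
  expect_true(all(diff(Te_a2) <= 1e-9))
  # both ideal or negatively deviating: Te never exceeds Tm2
  expect_true(all(Te_a1 <= 300 + 1e-9) && all(Te_a2 <= 300 + 1e-9))
})

test_that("exchanging the component labels mirrors the eutectic composition", {
  p_hi <- melting_properties(500, 18000)
  p_lo <- melting_properties(500, 9000)
  cf_hi <- rk_coefficients(-7000)
  ep <- eutectic_point(binary_system(p_hi, p_lo, coeffs1 = cf_hi))
  sw <- eutectic_point(binary_system(p_lo, p_hi, coeffs2 = cf_hi))
  expect_equal(sw$x1_e, 1 - ep$x1_e, tolerance = 1e-9)
  expect_equal(sw$Te, ep$Te, tolerance = 1e-9)
  expect_equal(sw$gamma2_e, ep$gamma1_e, tolerance = 1e-9)
})

test_that("positive-deviation coefficients are accepted with a warning", {
  expect_warning(
    binary_system(melting_properties(600, 32640), melting_properties(300, 16320),
                  rk_coefficients(5000)),
    "positive")
})

test_that("phase boundary table tracks the stable branch and the eutectic", {
  sys <- walden_600_300(a1 = -12000)
  ep <- eutectic_point(sys)
  tab <- phase_boundary_table(sys, grid = sort(c(seq(0, 1, by = 0.001), ep$x1_e)))
  expect_equal(tab$T_liquidus_K[tab$x1 == 1], 600)
  expect_equal(tab$stable_branch[tab$x1 == 1], 1L)
  expect_equal(tab$T_liquidus_K[tab$x1 == 0], 300)
  # at the eutectic both branches agree and the envelope minimum equals Te
  at_e <- tab[tab$x1 == ep$x1_e, ]
  expect_lt(abs(at_e$T1_K - at_e$T2_K), 1e-6)
  expect_equal(min(tab$T_liquidus_K, na.rm = TRUE), ep$Te, tolerance = 1e-6)
  # the stable branch flips exactly once for a simple eutectic
  expect_equal(sum(diff(tab$stable_branch) != 0), 1L)
})
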