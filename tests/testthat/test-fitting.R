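make_ideal_dataset <- function(Tm = 597, dHm = 4300, x = seq(0.3, 0.95, length.out = 8)) {
  p <- melting_properties(Tm, dHm)
  sle_dataset(data.frame(x1 = x, T_K = liquidus_temperature(x, p), branch = 1L))
}

test_that("ideal-solubility regression recovers the generating melting properties", {
  d <- make_ideal_dataset()
  fit <- fit_ideal_melting_properties(d)
  expect_equal(fit$dHm_hat, 4300, tolerance = 1e-8)
  expect_equal(fit$Tm_hat, 597, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # two points: an interpolating line with zero residuals
  d2 <- make_ideal_dataset(x = c(0.4, 0.8))
  f2 <- fit_ideal_melting_properties(d2)
  expect_equal(f2$r_squared, 1)
  expect_equal(f2$dHm_hat, 4300, tolerance = 1e-8)
  expect_error(fit_ideal_melting_properties(make_ideal_dataset(x = 0.5)),
               class = "slekit_fit_error")
})

test_that("pooled noisy family regression stays within sampling error of truth", {
  # Monte-Carlo: the pooled estimator across a 5-partner family is unbiased
  # for ideal data, so the mean recovered enthalpy over replicates must sit
  # within 3 standard errors of the truth
  shared <- melting_properties(597, 4300)
  partners <- lapply(c(320, 340, 360, 380, 400), function(Tm)
    list(props = melting_properties(Tm, walden_enthalpy(Tm))))
  reps <- 60
  est <- vapply(seq_len(reps), function(r) {
    fam <- simulate_shared_component_family(shared, partners, n_per_branch = 8L,
                                            sigma_T = 0.5, seed = 5000 + r,
                                            x1_range_branch1 = c(0.3, 0.95))
    fit_ideal_melting_properties(fam)$dHm_hat
  }, numeric(1))
  se <- stats::sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 4300), 3 * se + 1e-9)
})

test_that("compute_aad is the mean absolute temperature deviation, order-sensitive", {
  expect_identical(compute_aad(c(300, 310), c(300, 310)), 0)
  expect_identical(compute_aad(c(300, 310), c(302, 308)), 2)
  expect_identical(compute_aad(c(300, 310), c(310, 300)), 10)
  expect_error(compute_aad(1:3, 1:2), class = "slekit_domain_error")
})

test_that("Redlich-Kister regression recovers generating coefficients from clean data", {
  p <- melting_properties(600, 32640)
  x <- seq(0.25, 0.98, length.out = 14)
  true_ab <- c(-12000, -3000)
  T_K <- liquidus_temperature(x, p, rk_coefficients(true_ab))
  d <- sle_dataset(data.frame(x1 = x, T_K = T_K, branch = 1L))
  fit <- fit_rk_coefficients(d, p, n_terms = 2)
  expect_lt(max(abs(fit$coeffs$coeffs - true_ab) / abs(true_ab)), 1e-3)
  expect_lt(fit$objective, 1e-12)
  expect_lt(fit$aad, 1e-5)
  # ideal data with one term: the coefficient collapses to zero
  T_id <- liquidus_temperature(x, p)
  d_id <- sle_dataset(data.frame(x1 = x, T_K = T_id, branch = 1L))
  fit_id <- fit_rk_coefficients(d_id, p, n_terms = 1)
  expect_lt(abs(fit_id$coeffs$coeffs), 1)
  # a single point with one term is interpolated exactly
  d1 <- sle_dataset(data.frame(x1 = 0.5,
                               T_K = liquidus_temperature(0.5, p, rk_coefficients(-9000)),
                               branch = 1L))
  f1 <- fit_rk_coefficients(d1, p, n_terms = 1)
  expect_lt(f1$objective, 1e-18)
  expect_equal(f1$coeffs$coeffs, -9000, tolerance = 1e-4)
})

test_that("the fit objective is non-increasing in the number of terms", {
  p <- melting_properties(600, 32640)
  sys <- binary_system(p, melting_properties(300, 16320),
                       rk_coefficients(c(-15000, -4000, -1000)))
  d <- simulate_sle_dataset(generator_spec(sys, c(16L, 0L), sigma_T = 0.3,
                                           seed = 99,
                                           x1_range_branch1 = c(0.3, 0.97)))
  of <- vapply(1:3, function(k)
    fit_rk_coefficients(d, p, n_terms = k)$objective, numeric(1))
  expect_true(all(diff(of) <= 1e-12))
})

test_that("changing the assumed enthalpy shifts gamma by the exact reference-state factor", {
  d <- make_ideal_dataset(Tm = 597, dHm = 5000, x = seq(0.35, 0.95, length.out = 9))
  pA <- melting_properties(597, 5000)
  pB <- melting_properties(597, 40000)
  gA <- gamma_from_sle_point(d$x1, d$T_K, pA)
  gB <- gamma_from_sle_point(d$x1, d$T_K, pB)
  shift <- -(40000 - 5000) / R_GAS * (1 / d$T_K - 1 / 597)
  expect_equal(log(gB) - log(gA), shift, tolerance = 1e-12)
})

test_that("enthalpy screening singles out the generating enthalpy as quasi-ideal", {
  # data generated ideally at 5 kJ/mol over a wide composition span
  d <- make_ideal_dataset(Tm = 597, dHm = 5000, x = seq(0.35, 0.97, length.out = 12))
  x_e <- 0.35
  tab <- screen_melting_enthalpy(d, 597, c(1000, 5000, 10000, 20000),
                                 n_terms = 2, x_eutectic = x_e)
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$feasible))
  at <- function(dh) tab[tab$dHm_Jmol == dh, ]
  # the truth: near-zero objective and gamma at the eutectic composition ~ 1
  expect_lt(at(5000)$OF, 1e-12)
  expect_equal(at(5000)$gamma_at_xe, 1, tolerance = 1e-4)
  # an overestimated enthalpy drags gamma away from unity
  expect_lt(at(20000)$gamma_at_xe, 0.5)
  # a grossly underestimated one cannot reproduce the liquidus shape at all:
  # highest AAD of the grid
  expect_equal(which.max(tab$AAD_K), 1L)
  expect_gt(at(1000)$AAD_K, 10)
  # sanity at the extremes: the generating enthalpy beats both
  expect_lt(at(5000)$AAD_K, min(at(1000)$AAD_K, at(20000)$AAD_K))
  expect_error(screen_melting_enthalpy(d, 597, numeric(0), x_eutectic = 0.4),
               class = "slekit_domain_error")
})
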