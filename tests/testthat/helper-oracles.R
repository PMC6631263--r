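# Independent oracles and shared fixtures. The oracles re-derive every
# quantity from the thermodynamic relations directly, without calling the
# package functions they are used to check.

R_GAS <- 8.314462618

# Redlich-Kister polynomial written out by hand, J/mol
oracle_rk_poly <- function(xj, a = 0, b = 0, c = 0) {
  a * xj^2 + b * xj^3 + c * xj^4
}

# residual of the simplified liquidus relation, hand-coded
oracle_residual <- function(x, T, Tm, dHm, a = 0, b = 0, c = 0) {
  log(x) + oracle_rk_poly(1 - x, a, b, c) / (R_GAS * T) +
    dHm / R_GAS * (1 / T - 1 / Tm)
}

# liquidus temperature by bracketed root finding on the residual
oracle_liquidus_T <- function(x, Tm, dHm, a = 0, b = 0, c = 0, tol = 1e-9) {
  vapply(x, function(xi) {
    if (xi == 1) return(Tm)
    stats::uniroot(function(T) oracle_residual(xi, T, Tm, dHm, a, b, c),
                   lower = 1e-3, upper = Tm, tol = tol)$root
  }, numeric(1))
}

# eutectic by brute force: minimum of the upper envelope max(T1, T2) over a
# dense composition grid (log-dense near both pure ends), closed forms coded
# by hand
oracle_eutectic <- function(Tm1, dHm1, Tm2, dHm2, a1 = 0, a2 = 0,
                            n = 1e6, xmin = 1e-7) {
  g <- sort(unique(c(10^seq(log10(xmin), log10(0.5), length.out = n / 2),
                     1 - 10^seq(log10(xmin), log10(0.5), length.out = n / 2))))
  T1 <- (dHm1 + a1 * (1 - g)^2) / (dHm1 / Tm1 - R_GAS * log(g))
  T2 <- (dHm2 + a2 * g^2) / (dHm2 / Tm2 - R_GAS * log(1 - g))
  T1[dHm1 + a1 * (1 - g)^2 <= 0] <- NA
  T2[dHm2 + a2 * g^2 <= 0] <- NA
  env <- pmax(T1, T2, na.rm = TRUE)
  env[!is.finite(T1) & !is.finite(T2)] <- NA
  i <- which.min(env)
  list(x1_e = g[i], Te = env[i], dx = max(diff(g[max(1, i - 1):min(length(g), i + 1)])))
}

# canonical fixtures
walden_600_300 <- function(a1 = numeric(0), a2 = numeric(0)) {
  binary_system(
    melting_properties(600, walden_enthalpy(600)),
    melting_properties(300, walden_enthalpy(300)),
    rk_coefficients(a1), rk_coefficients(a2))
}

symmetric_system <- function(Tm = 400, dHm = 20000) {
  binary_system(melting_properties(Tm, dHm), melting_properties(Tm, dHm))
}
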