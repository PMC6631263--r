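#' Liquidus temperature from the simplified reference-state equation
#'
#' Solves `ln(x gamma) = -dHm/(R T) * (1 - T/Tm)` for the liquidus
#' temperature of the crystallizing component at liquid mole fraction `x`,
#' with the activity coefficient given by the Redlich-Kister polynomial.
#' Because `RT ln gamma` is temperature-independent under that polynomial,
#' the equation is linear in T and the solution is closed-form:
#' `T = (dHm + P(xj)) / (dHm/Tm - R ln x)` with `xj = 1 - x`.
#'
#' A strongly negative polynomial can drive the numerator `dHm + P(xj)` to
#' zero or below; no physical liquidus temperature exists there and a typed
#' error (`slekit_no_liquidus_error`) is raised unless `infeasible_na = TRUE`.
#'
#' @param x mole fraction of the crystallizing component in the liquid
#'   (vectorized), in `(0, 1]`.
#' @param props [melting_properties()] of the crystallizing component;
#'   `dCp` must be 0 (use [liquidus_temperature_full()] otherwise).
#' @param coeffs [rk_coefficients()] for this branch (default ideal).
#' @param infeasible_na return `NA` instead of erroring at infeasible
#'   compositions.
#' @return Liquidus temperature(s) in K. `x = 1` returns exactly `Tm`.
#' @examples
#' p1 <- melting_properties(600, walden_enthalpy(600))
#' liquidus_temperature(c(0.5, 1), p1)
#' liquidus_temperature(0.5, p1, rk_coefficients(-30000))
#' @export
liquidus_temperature <- function(x, props, coeffs = rk_coefficients(),
                                 infeasible_na = FALSE) {
  stopifnot(inherits(props, "melting_properties"))
  if (props$dCp != 0)
    stop_domain("`props$dCp` must be 0 for the closed-form liquidus; use liquidus_temperature_full()")
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x > 1))
    stop_domain("`x` must lie in (0, 1]")
  num <- props$dHm + rk_polynomial(1 - x, coeffs)
  den <- props$dHm / props$Tm - GAS_CONSTANT * log(x)
  T <- num / den
  bad <- num <= 0
  if (any(bad)) {
    if (!infeasible_na)
      stop_no_liquidus(sprintf(
        "no physical liquidus at x = %s: dHm + P(1 - x) <= 0 (over-strong negative deviation)",
        paste(signif(x[bad], 6), collapse = ", ")))
    T[bad] <- NA_real_
  }
  T
}

#' Residual of the full liquidus equation
#'
#' The full reference-state relation including the heat-capacity correction:
#' `ln(x gamma) + dHm/(R T) (1 - T/Tm) + dCp/R (1 - Tm/T + ln(Tm/T))`.
#' With `dCp = 0` this is exactly the residual of the simplified equation;
#' its root in T is the liquidus temperature.
#'
#' @param x mole fraction of the crystallizing component, in `(0, 1]`.
#' @param T temperature, K (vectorized with `x`).
#' @param props [melting_properties()] (its `dCp` enters the correction term).
#' @param coeffs [rk_coefficients()] for this branch.
#' @return Dimensionless residual; 0 on the liquidus line.
#' @export
full_liquidus_residual <- function(x, T, props, coeffs = rk_coefficients()) {
  stopifnot(inherits(props, "melting_properties"))
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x > 1))
    stop_domain("`x` must lie in (0, 1]")
  if (!is.numeric(T) || any(!is.finite(T)) || any(T <= 0))
    stop_domain("`T` must be positive (K)")
  lhs <- log(x) + rk_log_gamma(1 - x, coeffs, T)
  rhs <- -props$dHm / (GAS_CONSTANT * T) * (1 - T / props$Tm) -
    props$dCp / GAS_CONSTANT * (1 - props$Tm / T + log(props$Tm / T))
  lhs - rhs
}

#' Liquidus temperature from the full equation (heat-capacity correction)
#'
#' Finds the root of [full_liquidus_residual()] in T by bracketed iteration
#' on `(1 K, Tm]`. With `dCp = 0` the result agrees with the closed-form
#' [liquidus_temperature()] to well below 1e-6 K; with `dCp != 0` this is the
#' only available solver.
#'
#' @inheritParams liquidus_temperature
#' @param tol absolute tolerance on T, K.
#' @return Liquidus temperature(s) in K.
#' @export
liquidus_temperature_full <- function(x, props, coeffs = rk_coefficients(),
                                      tol = 1e-8, infeasible_na = FALSE) {
  stopifnot(inherits(props, "melting_properties"))
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x > 1))
    stop_domain("`x` must lie in (0, 1]")
  vapply(x, function(xi) {
    if (xi == 1 && length(rk_coefficients(coeffs)$coeffs) >= 0) {
      # residual vanishes identically at (x, T) = (1, Tm)
      if (abs(full_liquidus_residual(1, props$Tm, props, coeffs)) < 1e-12)
        return(props$Tm)
    }
    # scan downward from Tm: a large heat-capacity correction can bend the
    # residual back, so the physical root is the first sign change below Tm
    Ts <- seq(props$Tm, 1, length.out = 400L)
    fs <- full_liquidus_residual(xi, Ts, props, coeffs)
    br <- which(is.finite(fs[-length(fs)]) & is.finite(fs[-1]) &
                  fs[-length(fs)] * fs[-1] <= 0)
    if (length(br) == 0L) {
      if (infeasible_na) return(NA_real_)
      stop_no_liquidus(sprintf(
        "no liquidus root bracketed on (1 K, Tm] at x = %.6g", xi))
    }
    stats::uniroot(function(T) full_liquidus_residual(xi, T, props, coeffs),
                   lower = Ts[br[1] + 1L], upper = Ts[br[1]], tol = tol)$root
  }, numeric(1))
}

#' Experimental activity coefficient from a measured SLE point
#'
#' Inverts the simplified liquidus equation at a measured point `(x, T)`:
#' `gamma = exp(-dHm/R * (1/T - 1/Tm)) / x`. This is the "experimental"
#' activity coefficient the Redlich-Kister regression targets; its value
#' depends on the assumed melting properties through the reference state.
#'
#' @param x liquid mole fraction of the crystallizing component, in `(0, 1]`
#'   (vectorized).
#' @param T measured liquidus temperature, K (vectorized with `x`).
#' @param props assumed [melting_properties()] of the crystallizing component.
#' @return Activity coefficient(s), dimensionless and strictly positive.
#' @examples
#' p <- melting_properties(597, 4300)
#' gamma_from_sle_point(0.6, liquidus_temperature(0.6, p), p) # 1 (ideal data)
#' @export
gamma_from_sle_point <- function(x, T, props) {
  stopifnot(inherits(props, "melting_properties"))
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x > 1))
    stop_domain("`x` must lie in (0, 1]")
  if (!is.numeric(T) || any(!is.finite(T)) || any(T <= 0))
    stop_domain("`T` must be positive (K)")
  exp(-props$dHm / GAS_CONSTANT * (1 / T - 1 / props$Tm)) / x
}
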