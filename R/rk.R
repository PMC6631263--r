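#' Redlich-Kister activity-coefficient parameters for one liquidus branch
#'
#' The liquid-phase non-ideality of component i is described empirically by a
#' Redlich-Kister polynomial in the mole fraction of the other component,
#' `RT ln(gamma_i) = a xj^2 + b xj^3 + c xj^4`, with up to three energetic
#' coefficients in J/mol. An empty coefficient set means ideal behaviour
#' (`ln gamma == 0`). Negative coefficients describe favoured unlike-pair
#' interactions (negative deviation from ideality, `gamma < 1`), the regime
#' relevant to deep eutectic solvents; positive entries are accepted but
#' flagged with a warning by the phase-diagram layer.
#'
#' @param coeffs numeric vector of length 0 to 3: the `a`, `b`, `c`
#'   coefficients in J/mol, in that order. Missing trailing terms are zero.
#' @return An object of class `"rk_coefficients"`.
#' @examples
#' rk_coefficients()          # ideal
#' rk_coefficients(-30000)    # one-parameter, strong negative deviation
#' rk_coefficients(c(-5000, 2000, -100))
#' @export
rk_coefficients <- function(coeffs = numeric(0)) {
  if (inherits(coeffs, "rk_coefficients")) return(coeffs)
  if (!is.numeric(coeffs) || length(coeffs) > 3L || any(!is.finite(coeffs)))
    stop_domain("`coeffs` must be 0 to 3 finite energies (J/mol) in a, b, c order")
  structure(list(coeffs = as.numeric(coeffs)), class = "rk_coefficients")
}

#' @export
print.rk_coefficients <- function(x, ...) {
  if (length(x$coeffs) == 0L) {
    cat("Redlich-Kister coefficients: ideal (ln gamma = 0)\n")
  } else {
    cat("Redlich-Kister coefficients (J/mol):",
        paste(sprintf("%.10g", x$coeffs), collapse = ", "), "\n")
  }
  invisible(x)
}

# the polynomial P(xj) = a xj^2 + b xj^3 + c xj^4 in J/mol (vectorized in xj)
rk_polynomial <- function(xj, coeffs) {
  cf <- rk_coefficients(coeffs)$coeffs
  out <- numeric(length(xj))
  for (k in seq_along(cf)) out <- out + cf[k] * xj^(k + 1)
  out
}

#' Redlich-Kister log activity coefficient
#'
#' Evaluates `ln gamma_i = (a xj^2 + b xj^3 + c xj^4) / (R T)` where `xj` is
#' the mole fraction of the other component. An empty coefficient set returns
#' exactly 0 (ideal solution).
#'
#' @param xj mole fraction of the other component (vectorized), in `[0, 1]`.
#' @param coeffs an [rk_coefficients()] object or a bare numeric vector.
#' @param T temperature, K; must be > 0.
#' @return `ln gamma`, dimensionless.
#' @examples
#' rk_log_gamma(0.5, rk_coefficients(-30000), 300)
#' @export
rk_log_gamma <- function(xj, coeffs, T) {
  if (!is.numeric(xj) || any(!is.finite(xj)) || any(xj < 0) || any(xj > 1))
    stop_domain("`xj` must lie in [0, 1]")
  if (!is.numeric(T) || any(!is.finite(T)) || any(T <= 0))
    stop_domain("`T` must be a positive temperature in K")
  rk_polynomial(xj, coeffs) / (GAS_CONSTANT * T)
}
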