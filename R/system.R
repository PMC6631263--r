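#' Binary eutectic system definition
#'
#' Pairs the melting properties and branch-wise Redlich-Kister coefficients of
#' the two components. By convention Component 1 is the high-melting
#' component (`props1$Tm >= props2$Tm`). Each liquidus branch carries its own
#' independent coefficient set; no Gibbs-Duhem cross-consistency is imposed,
#' matching the empirical use of the polynomial.
#'
#' @param props1,props2 [melting_properties()] of Components 1 and 2.
#' @param coeffs1,coeffs2 [rk_coefficients()] of the two branches (default
#'   ideal). Positive entries (positive deviation from ideality) are accepted
#'   with a warning; the DES screening context considers only negative
#'   deviations.
#' @param name1,name2 component labels.
#' @return An object of class `"binary_system"`.
#' @examples
#' ideal_walden <- binary_system(
#'   melting_properties(600, walden_enthalpy(600)),
#'   melting_properties(300, walden_enthalpy(300)))
#' @export
binary_system <- function(props1, props2,
                          coeffs1 = rk_coefficients(),
                          coeffs2 = rk_coefficients(),
                          name1 = "Component 1", name2 = "Component 2") {
  stopifnot(inherits(props1, "melting_properties"),
            inherits(props2, "melting_properties"))
  coeffs1 <- rk_coefficients(coeffs1)
  coeffs2 <- rk_coefficients(coeffs2)
  if (props1$Tm < props2$Tm)
    stop_domain("Component 1 must be the high-melting component (Tm1 >= Tm2)")
  if (any(coeffs1$coeffs > 0) || any(coeffs2$coeffs > 0))
    warning("positive Redlich-Kister entries: positive deviation from ideality",
            call. = FALSE)
  structure(
    list(props1 = props1, props2 = props2, coeffs1 = coeffs1, coeffs2 = coeffs2,
         name1 = name1, name2 = name2),
    class = "binary_system"
  )
}

#' @export
print.binary_system <- function(x, ...) {
  cat(sprintf("Binary system: %s (1) / %s (2)\n", x$name1, x$name2))
  cat(sprintf("  1: Tm = %.10g K, dHm = %.10g J/mol, RK = [%s]\n",
              x$props1$Tm, x$props1$dHm,
              paste(sprintf("%g", x$coeffs1$coeffs), collapse = ", ")))
  cat(sprintf("  2: Tm = %.10g K, dHm = %.10g J/mol, RK = [%s]\n",
              x$props2$Tm, x$props2$dHm,
              paste(sprintf("%g", x$coeffs2$coeffs), collapse = ", ")))
  invisible(x)
}

# branch liquidus as a function of x1; NA where infeasible
branch_temperature <- function(system, branch, x1) {
  if (branch == 1L) {
    liquidus_temperature(x1, system$props1, system$coeffs1, infeasible_na = TRUE)
  } else {
    liquidus_temperature(1 - x1, system$props2, system$coeffs2, infeasible_na = TRUE)
  }
}

#' Liquidus curve of one branch
#'
#' Evaluates one branch's liquidus temperature over a grid of Component-1
#' mole fractions. For branch 1 the crystallizing component's mole fraction
#' is `x1`; for branch 2 it is `1 - x1`. Compositions where the branch has no
#' physical liquidus (over-strong negative deviation) are flagged infeasible
#' and carry `NA` temperature.
#'
#' @param system a [binary_system()].
#' @param branch which solid crystallizes, 1 or 2.
#' @param grid Component-1 mole fractions; branch 1 requires `x1 > 0`,
#'   branch 2 requires `x1 < 1`.
#' @return A data frame `(x1, T_K, branch, feasible)`.
#' @export
liquidus_curve <- function(system, branch, grid) {
  stopifnot(inherits(system, "binary_system"))
  if (!branch %in% c(1L, 2L)) stop_domain("`branch` must be 1 or 2")
  if (length(grid) == 0L) stop_domain("`grid` must be non-empty")
  lo_ok <- if (branch == 1L) all(grid > 0) else all(grid < 1)
  if (!lo_ok || any(grid < 0) || any(grid > 1))
    stop_domain("grid values must keep the crystallizing component's x in (0, 1]")
  T_K <- branch_temperature(system, as.integer(branch), grid)
  data.frame(x1 = grid, T_K = T_K, branch = as.integer(branch),
             feasible = is.finite(T_K))
}

#' Normalized depression at the eutectic point
#'
#' `(Tm_ref - Te) / Tm_ref`, the dimensionless measure of how deep a eutectic
#' sits below a reference melting temperature, conventionally that of the
#' low-melting component.
#'
#' @param Te eutectic temperature, K.
#' @param Tm_ref reference melting temperature, K.
#' @return Dimensionless depression (0 for no depression).
#' @export
normalized_depression <- function(Te, Tm_ref) {
  if (!is.numeric(Te) || any(!is.finite(Te)) || any(Te <= 0))
    stop_domain("`Te` must be positive (K)")
  if (!is.numeric(Tm_ref) || any(!is.finite(Tm_ref)) || any(Tm_ref <= 0))
    stop_domain("`Tm_ref` must be positive (K)")
  (Tm_ref - Te) / Tm_ref
}
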