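#' Pure-component melting properties
#'
#' Bundle the reference-state parameters of a crystallizing component: melting
#' temperature `Tm` (K), melting enthalpy `dHm` (J/mol) and, optionally, the
#' heat-capacity difference between the subcooled liquid and the solid,
#' `dCp` (J/(mol K), liquid minus solid, default 0). The melting enthalpy can
#' be given directly, or derived from a melting entropy `dSm` (J/(mol K)) as
#' `dHm = dSm * Tm`.
#'
#' @param Tm melting temperature, K; must be > 0.
#' @param dHm melting enthalpy, J/mol; must be > 0. Exactly one of `dHm`,
#'   `dSm` must be supplied.
#' @param dSm melting entropy, J/(mol K); if supplied, `dHm = dSm * Tm`.
#' @param dCp heat-capacity difference cp(liquid) - cp(solid), J/(mol K).
#'   Default 0, which reduces the liquidus equation to its commonly used
#'   simplified form.
#'
#' @return An object of class `"melting_properties"`: a list with elements
#'   `Tm`, `dHm`, `dCp` and the derived entropy `dSm = dHm / Tm`.
#'
#' @examples
#' melting_properties(Tm = 600, dHm = walden_enthalpy(600))
#' melting_properties(Tm = 300, dSm = 20)
#' @export
melting_properties <- function(Tm, dHm = NULL, dSm = NULL, dCp = 0) {
  if (!is.numeric(Tm) || length(Tm) != 1L || !is.finite(Tm) || Tm <= 0)
    stop_domain("`Tm` must be a single finite positive temperature in K")
  if (is.null(dHm) == is.null(dSm))
    stop_domain("supply exactly one of `dHm` (J/mol) or `dSm` (J/(mol K))")
  if (is.null(dHm)) {
    if (!is.numeric(dSm) || length(dSm) != 1L || !is.finite(dSm) || dSm <= 0)
      stop_domain("`dSm` must be a single finite positive entropy in J/(mol K)")
    dHm <- dSm * Tm
  }
  if (!is.numeric(dHm) || length(dHm) != 1L || !is.finite(dHm) || dHm <= 0)
    stop_domain("`dHm` must be a single finite positive enthalpy in J/mol")
  if (!is.numeric(dCp) || length(dCp) != 1L || !is.finite(dCp))
    stop_domain("`dCp` must be a single finite value in J/(mol K)")
  structure(
    list(Tm = as.numeric(Tm), dHm = as.numeric(dHm), dCp = as.numeric(dCp),
         dSm = as.numeric(dHm / Tm)),
    class = "melting_properties"
  )
}

#' @export
print.melting_properties <- function(x, ...) {
  cat(sprintf(
    "Melting properties: Tm = %.10g K, dHm = %.10g J/mol (dSm = %.10g J/(mol K)), dCp = %.10g J/(mol K)\n",
    x$Tm, x$dHm, x$dSm, x$dCp))
  invisible(x)
}

#' Melting enthalpy from the Walden rule
#'
#' The Walden rule states that rigid organic molecules have an approximately
#' constant melting entropy of 54.4 J/(mol K), so the melting enthalpy follows
#' from the melting temperature alone: `dHm = 54.4 * Tm`.
#'
#' @param Tm melting temperature, K (vectorized); must be >= 0.
#' @return Melting enthalpy in J/mol.
#' @examples
#' walden_enthalpy(600) # 32640 J/mol
#' @seealso [enthalpy_from_entropy()] for an arbitrary fixed melting entropy.
#' @export
walden_enthalpy <- function(Tm) {
  enthalpy_from_entropy(Tm, 54.4)
}

#' Melting enthalpy from a fixed melting entropy
#'
#' `dHm = dSm * Tm`. A low entropy (around 20 J/(mol K)) is typical of
#' disordered crystals of rigid molecules; 54.4 J/(mol K) is the Walden value
#' for ordered crystals.
#'
#' @param Tm melting temperature, K (vectorized); must be >= 0.
#' @param dSm melting entropy, J/(mol K); must be >= 0.
#' @return Melting enthalpy in J/mol.
#' @examples
#' enthalpy_from_entropy(600, 20) # 12000 J/mol
#' @export
enthalpy_from_entropy <- function(Tm, dSm) {
  if (!is.numeric(Tm) || any(!is.finite(Tm)) || any(Tm < 0))
    stop_domain("`Tm` must be finite and non-negative (K)")
  if (!is.numeric(dSm) || any(!is.finite(dSm)) || any(dSm < 0))
    stop_domain("`dSm` must be finite and non-negative (J/(mol K))")
  dSm * Tm
}
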