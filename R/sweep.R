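# named melting-entropy conventions: Walden (ordered crystals of rigid
# molecules) and the low value typical of disordered crystals
resolve_dSm <- function(x) {
  if (is.character(x)) {
    switch(x,
           walden = 54.4,
           low = 20.0,
           stop_domain(sprintf("unknown entropy convention '%s' (use 'walden', 'low' or a number)", x)))
  } else if (is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0) {
    x
  } else {
    stop_domain("entropy convention must be 'walden', 'low' or a positive number")
  }
}

#' Configuration for a eutectic parameter sweep
#'
#' Defines the grids of a parameter study over melting properties and
#' (optionally) liquid-phase non-ideality. Melting enthalpies are taken from
#' explicit `dHm1`/`dHm2` grids when supplied, otherwise derived from the
#' melting temperature and the per-component entropy convention
#' (`"walden"` = 54.4 J/(mol K), `"low"` = 20.0 J/(mol K), or a number).
#' One-parameter Redlich-Kister grids `a1`, `a2` (J/mol, <= 0 for the DES
#' regime) describe the non-ideality of each branch; `a = 0` is the ideal
#' case.
#'
#' @param mode `"ideal"` (all `a` forced to 0) or `"nonideal"`.
#' @param Tm1,Tm2 melting-temperature grids, K (Component 1 is high-melting;
#'   nodes with `Tm1 < Tm2` are flagged infeasible, not swapped).
#' @param dSm1,dSm2 entropy conventions per component (scalars or vectors of
#'   names/numbers). Ignored for a component with an explicit enthalpy grid.
#' @param dHm1,dHm2 optional explicit enthalpy grids, J/mol.
#' @param a1,a2 one-parameter Redlich-Kister grids, J/mol.
#' @return An object of class `"sweep_config"`.
#' @examples
#' sweep_config("ideal", Tm1 = 300 * seq(1, 3, 0.5), Tm2 = 300,
#'              dSm1 = "walden", dSm2 = "walden")
#' @export
sweep_config <- function(mode = c("ideal", "nonideal"),
                         Tm1 = 600, Tm2 = 300,
                         dSm1 = "walden", dSm2 = "walden",
                         dHm1 = NULL, dHm2 = NULL,
                         a1 = 0, a2 = 0) {
  mode <- match.arg(mode)
  if (length(Tm1) == 0L || length(Tm2) == 0L) stop_domain("temperature grids must be non-empty")
  if (mode == "ideal") { a1 <- 0; a2 <- 0 }
  if (length(a1) == 0L || length(a2) == 0L) stop_domain("`a1`/`a2` grids must be non-empty")
  structure(
    list(mode = mode, Tm1 = Tm1, Tm2 = Tm2,
         dSm1 = dSm1, dSm2 = dSm2, dHm1 = dHm1, dHm2 = dHm2,
         a1 = a1, a2 = a2),
    class = "sweep_config"
  )
}

#' Default non-ideality sweep configuration
#'
#' The four-case study of a hypothetical 600 K / 300 K pair: Component-1
#' enthalpy from the Walden rule (32 640 J/mol) or a low melting entropy of
#' 20 J/(mol K) (12 000 J/mol), crossed with Component-2 enthalpy 16 320 or
#' 6 000 J/mol, over one-parameter Redlich-Kister grids
#' `a in {0, -6000, ..., -30000}` J/mol on both branches.
#'
#' @return A `"sweep_config"` in `"nonideal"` mode.
#' @export
default_nonideality_config <- function() {
  sweep_config("nonideal", Tm1 = 600, Tm2 = 300,
               dHm1 = c(32640, 12000), dHm2 = c(16320, 6000),
               a1 = seq(0, -30000, by = -6000),
               a2 = seq(0, -30000, by = -6000))
}

#' Default ideal sweep configuration
#'
#' Melting-temperature ratio grid `Tm1/Tm2` from 1 to 3 in steps of 0.25 at
#' `Tm2 = 300 K`, crossed with the Walden (54.4) and low (20.0 J/(mol K))
#' melting-entropy conventions on both components.
#'
#' @return A `"sweep_config"` in `"ideal"` mode.
#' @export
default_ideal_config <- function() {
  sweep_config("ideal", Tm1 = 300 * seq(1, 3, by = 0.25), Tm2 = 300,
               dSm1 = c(54.4, 20.0), dSm2 = c(54.4, 20.0))
}

# expand a config into one data frame row per grid node
sweep_nodes <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  enth1 <- if (is.null(config$dHm1)) {
    data.frame(dSm1 = vapply(config$dSm1, resolve_dSm, numeric(1)), dHm1 = NA_real_)
  } else data.frame(dSm1 = NA_real_, dHm1 = config$dHm1)
  enth2 <- if (is.null(config$dHm2)) {
    data.frame(dSm2 = vapply(config$dSm2, resolve_dSm, numeric(1)), dHm2 = NA_real_)
  } else data.frame(dSm2 = NA_real_, dHm2 = config$dHm2)
  nodes <- expand.grid(Tm1_K = config$Tm1, Tm2_K = config$Tm2,
                       i1 = seq_len(nrow(enth1)), i2 = seq_len(nrow(enth2)),
                       a1_Jmol = config$a1, a2_Jmol = config$a2,
                       KEEP.OUT.ATTRS = FALSE)
  nodes <- cbind(nodes, enth1[nodes$i1, , drop = FALSE],
                 enth2[nodes$i2, , drop = FALSE])
  nodes$i1 <- NULL; nodes$i2 <- NULL
  rownames(nodes) <- NULL
  nodes$dHm1_Jmol <- ifelse(is.na(nodes$dHm1), nodes$dSm1 * nodes$Tm1_K, nodes$dHm1)
  nodes$dHm2_Jmol <- ifelse(is.na(nodes$dHm2), nodes$dSm2 * nodes$Tm2_K, nodes$dHm2)
  nodes$dHm1 <- NULL; nodes$dHm2 <- NULL
  nodes
}

run_sweep <- function(config) {
  nodes <- sweep_nodes(config)
  res <- lapply(seq_len(nrow(nodes)), function(i) {
    nd <- nodes[i, ]
    if (nd$Tm1_K < nd$Tm2_K)
      return(data.frame(x1_e = NA_real_, Te_K = NA_real_,
                        norm_depression = NA_real_, feasible = FALSE))
    ep <- tryCatch({
      sys <- binary_system(
        melting_properties(nd$Tm1_K, nd$dHm1_Jmol),
        melting_properties(nd$Tm2_K, nd$dHm2_Jmol),
        rk_coefficients(if (nd$a1_Jmol != 0) nd$a1_Jmol else numeric(0)),
        rk_coefficients(if (nd$a2_Jmol != 0) nd$a2_Jmol else numeric(0)))
      eutectic_point(sys)
    }, slekit_error = function(e) NULL)
    if (is.null(ep))
      data.frame(x1_e = NA_real_, Te_K = NA_real_,
                 norm_depression = NA_real_, feasible = FALSE)
    else
      data.frame(x1_e = ep$x1_e, Te_K = ep$Te,
                 norm_depression = ep$norm_depression, feasible = TRUE)
  })
  out <- cbind(mode = config$mode, nodes, do.call(rbind, res))
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Run an ideal-solution parameter sweep
#'
#' Solves the eutectic point of an ideal binary system (`gamma = 1`) at every
#' node of the configured melting-property grids and tabulates the eutectic
#' composition, temperature and normalized depression. The sweep is
#' deterministic and reproducible bit-for-bit from its configuration.
#'
#' @param config a [sweep_config()] in `"ideal"` mode (default
#'   [default_ideal_config()]).
#' @return A long-format data frame with one row per grid node: all swept
#'   inputs plus `x1_e`, `Te_K`, `norm_depression`, `feasible`.
#' @export
run_ideal_sweep <- function(config = default_ideal_config()) {
  stopifnot(inherits(config, "sweep_config"))
  if (config$mode != "ideal") stop_domain("`config$mode` must be 'ideal'")
  run_sweep(config)
}

#' Run a non-ideality parameter sweep
#'
#' Like [run_ideal_sweep()] but over one-parameter Redlich-Kister grids on
#' both branches, covering the interplay of melting enthalpy and liquid-phase
#' non-ideality. Nodes where a branch (or the eutectic) becomes infeasible
#' under over-strong negative deviation are flagged, not dropped.
#'
#' @param config a [sweep_config()] in `"nonideal"` mode (default
#'   [default_nonideality_config()]).
#' @return A long-format data frame, one row per grid node.
#' @export
run_nonideality_sweep <- function(config = default_nonideality_config()) {
  stopifnot(inherits(config, "sweep_config"))
  if (config$mode != "nonideal") stop_domain("`config$mode` must be 'nonideal'")
  run_sweep(config)
}
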