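# composition scan grid: linear core with log-dense tails toward both pure
# ends, because ideal eutectics of dissimilar pairs sit extremely close to a
# pure side
eutectic_scan_grid <- function(n = 2001L, xmin = 1e-6) {
  n_tail <- max(50L, floor(n / 4))
  n_core <- n - 2L * n_tail
  tail_lo <- 10^seq(log10(xmin), log10(0.05), length.out = n_tail)
  core <- seq(0.05, 0.95, length.out = n_core)
  tail_hi <- 1 - rev(tail_lo)
  sort(unique(c(tail_lo, core, tail_hi)))
}

#' Locate the eutectic point of a binary system
#'
#' The eutectic is the intersection of the two liquidus branches, equivalently
#' the minimum of the upper envelope `max(T1, T2)`. It is located by a dense
#' composition scan (log-dense near both pure ends) followed by bisection
#' refinement of every sign change of `D(x) = T1(x) - T2(x)`; when several
#' intersections exist (possible with strong non-ideality) the one with the
#' lowest temperature is returned with a warning.
#'
#' @param system a [binary_system()].
#' @param n_scan number of scan points (default 2001).
#' @param xmin smallest distance to a pure end probed by the scan.
#' @return An object of class `"eutectic_point"`: list with `x1_e` (mole
#'   fraction of Component 1), `Te` (K), `norm_depression`
#'   (`(Tm2 - Te)/Tm2`, relative to the low-melting component), and the
#'   branch activity coefficients `gamma1_e`, `gamma2_e` at the eutectic.
#' @examples
#' sys <- binary_system(
#'   melting_properties(600, walden_enthalpy(600)),
#'   melting_properties(300, walden_enthalpy(300)))
#' eutectic_point(sys)
#' @export
eutectic_point <- function(system, n_scan = 2001L, xmin = 1e-6) {
  stopifnot(inherits(system, "binary_system"))
  grid <- eutectic_scan_grid(n_scan, xmin)
  T1 <- branch_temperature(system, 1L, grid)
  T2 <- branch_temperature(system, 2L, grid)
  D <- T1 - T2
  ok <- is.finite(D)
  if (!any(ok))
    stop_no_eutectic("both branches infeasible over the entire scan grid")
  Dfun <- function(x) {
    t1 <- branch_temperature(system, 1L, x)
    t2 <- branch_temperature(system, 2L, x)
    t1 - t2
  }
  # brackets: consecutive feasible scan points with a sign change
  idx <- which(ok[-length(ok)] & ok[-1] & D[-length(D)] * D[-1] <= 0 &
                 D[-length(D)] != 0)
  roots <- vapply(idx, function(i) {
    lo <- grid[i]; hi <- grid[i + 1]
    flo <- D[i]
    # bisection to machine precision on x; D is cheap and closed-form
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      if (mid <= lo || mid >= hi) break
      fm <- Dfun(mid)
      if (!is.finite(fm)) break
      if (fm == 0) { lo <- mid; hi <- mid; break }
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  exact <- grid[which(ok & D == 0)]
  roots <- c(roots, exact)
  if (length(roots) == 0L)
    stop_no_eutectic("liquidus branches do not intersect on (0, 1): no eutectic")
  Te_all <- branch_temperature(system, 1L, roots)
  if (length(roots) > 1L &&
      diff(range(roots)) > 1e-9) {
    warning("multiple liquidus intersections found; returning the lowest-temperature one",
            call. = FALSE)
  }
  best <- which.min(Te_all)
  x_e <- roots[best]
  Te <- Te_all[best]
  structure(
    list(
      x1_e = x_e,
      Te = Te,
      norm_depression = normalized_depression(Te, system$props2$Tm),
      gamma1_e = exp(rk_log_gamma(1 - x_e, system$coeffs1, Te)),
      gamma2_e = exp(rk_log_gamma(x_e, system$coeffs2, Te)),
      system = system
    ),
    class = "eutectic_point"
  )
}

#' @export
print.eutectic_point <- function(x, ...) {
  cat(sprintf(
    paste0("Eutectic point: x1_e = %.10g, Te = %.10g K\n",
           "  normalized depression (vs Tm2) = %.10g\n",
           "  gamma1(e) = %.10g, gamma2(e) = %.10g\n"),
    x$x1_e, x$Te, x$norm_depression, x$gamma1_e, x$gamma2_e))
  invisible(x)
}

#' Phase-boundary (upper-envelope) table
#'
#' Tabulates both branch temperatures over a composition grid together with
#' the stable liquidus `max(T1, T2)` and which branch provides it. The
#' envelope's minimum over the grid approximates the eutectic temperature to
#' grid resolution.
#'
#' @param system a [binary_system()].
#' @param grid Component-1 mole fractions in `(0, 1)`, or the endpoints 0/1
#'   (each endpoint is evaluated on the branch it belongs to).
#' @return Data frame `(x1, T1_K, T2_K, T_liquidus_K, stable_branch,
#'   feasible)`; `stable_branch` is `NA` where neither branch is feasible.
#' @export
phase_boundary_table <- function(system, grid = eutectic_scan_grid()) {
  stopifnot(inherits(system, "binary_system"))
  if (length(grid) == 0L) stop_domain("`grid` must be non-empty")
  if (any(grid < 0) || any(grid > 1)) stop_domain("grid values must lie in [0, 1]")
  T1 <- rep(NA_real_, length(grid))
  T2 <- rep(NA_real_, length(grid))
  in1 <- grid > 0
  in2 <- grid < 1
  T1[in1] <- branch_temperature(system, 1L, grid[in1])
  T2[in2] <- branch_temperature(system, 2L, grid[in2])
  T_liq <- pmax(T1, T2, na.rm = TRUE)
  T_liq[!is.finite(T1) & !is.finite(T2)] <- NA_real_
  stable <- ifelse(!is.finite(T_liq), NA_integer_,
                   ifelse(is.finite(T1) & (!is.finite(T2) | T1 >= T2), 1L, 2L))
  data.frame(x1 = grid, T1_K = T1, T2_K = T2, T_liquidus_K = T_liq,
             stable_branch = stable, feasible = is.finite(T_liq))
}
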