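#' Back-estimate melting properties from ideal solubility
#'
#' Under the ideal-solution model the liquidus obeys
#' `ln x1 = dHm/(R Tm) - dHm/R * (1/T)`, so `ln x1` against `1/T` is a
#' straight line whose slope gives the melting enthalpy (`dHm = -R * slope`)
#' and whose intercept, combined with the slope, gives the melting
#' temperature (`Tm = -slope / intercept`). This is the standard indirect
#' route to the melting properties of thermally unstable components (e.g.
#' choline chloride) from their solubility in several partners.
#'
#' @param datasets a single [sle_dataset()] or a list of them (a
#'   shared-component family, each with the shared component as Component 1).
#' @param pooled if `TRUE` (default) all branch-1 points are concatenated
#'   into one regression; if `FALSE` each dataset is fitted separately and a
#'   list of fits is returned.
#' @return An object of class `"melting_fit"` (or a list of them): `dHm_hat`
#'   (J/mol), `Tm_hat` (K), `r_squared`, `slope`, `intercept`, `n_points`.
#' @examples
#' p <- melting_properties(597, 4300)
#' x <- seq(0.3, 0.95, length.out = 8)
#' d <- sle_dataset(data.frame(x1 = x, T_K = liquidus_temperature(x, p), branch = 1))
#' fit_ideal_melting_properties(d)
#' @export
fit_ideal_melting_properties <- function(datasets, pooled = TRUE) {
  if (inherits(datasets, "sle_dataset")) datasets <- list(datasets)
  stopifnot(is.list(datasets), all(vapply(datasets, inherits, TRUE, "sle_dataset")))
  if (!pooled) {
    fits <- lapply(datasets, fit_ideal_melting_properties, pooled = TRUE)
    names(fits) <- vapply(datasets, function(d) attr(d, "name2"), character(1))
    return(fits)
  }
  pts <- do.call(rbind, lapply(datasets, function(d) {
    b <- branch_points(d, 1L, interior_only = FALSE)
    b[b$x > 0, c("x", "T_K")]
  }))
  if (nrow(unique(pts)) < 2L)
    stop_fit("need at least 2 distinct branch-1 points for the ideal-solubility regression")
  fit <- stats::lm(log(x) ~ I(1 / T_K), data = pts)
  s <- unname(stats::coef(fit)[2])
  c0 <- unname(stats::coef(fit)[1])
  if (!is.finite(s) || !is.finite(c0) || c0 == 0)
    stop_fit("degenerate ideal-solubility fit (zero or undefined intercept)")
  sst <- sum((log(pts$x) - mean(log(pts$x)))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(
    list(dHm_hat = -GAS_CONSTANT * s, Tm_hat = -s / c0, r_squared = r2,
         slope = s, intercept = c0, n_points = nrow(pts)),
    class = "melting_fit"
  )
}

#' @export
print.melting_fit <- function(x, ...) {
  cat(sprintf(
    "Ideal-solubility melting fit (n = %d): dHm = %.10g J/mol, Tm = %.10g K, R^2 = %.6f\n",
    x$n_points, x$dHm_hat, x$Tm_hat, x$r_squared))
  invisible(x)
}

#' Average absolute deviation between liquidus temperatures
#'
#' `AAD = mean(|T_calc - T_exp|)` in K, the conventional figure of merit for
#' an SLE fit. Inputs are paired positionally; order matters.
#'
#' @param T_calc,T_exp calculated and experimental temperatures, K, of equal
#'   length.
#' @return Mean absolute deviation, K.
#' @export
compute_aad <- function(T_calc, T_exp) {
  if (length(T_calc) != length(T_exp))
    stop_domain("`T_calc` and `T_exp` must have equal length")
  if (length(T_calc) == 0L) stop_domain("need at least one point")
  mean(abs(T_calc - T_exp))
}

# closed-form linear least squares for the RK coefficients in RT*ln(gamma)
# space: RT ln(gamma) = a xj^2 + b xj^3 + c xj^4 is linear in (a, b, c)
rk_linear_seed <- function(xj, rt_lngamma, n_terms) {
  X <- vapply(seq_len(n_terms) + 1L, function(p) xj^p,
              numeric(length(xj)))
  X <- matrix(X, nrow = length(xj))
  cf <- qr.coef(qr(X), rt_lngamma)
  cf[!is.finite(cf)] <- 0
  cf
}

#' Fit Redlich-Kister coefficients to SLE data
#'
#' Estimates the branch-1 Redlich-Kister coefficients by minimizing the
#' activity-coefficient objective `OF = sum((gamma_calc - gamma_exp)^2)`,
#' where `gamma_exp` comes from [gamma_from_sle_point()] under the assumed
#' melting properties and `gamma_calc = exp(P(xj) / (R T))` from the
#' polynomial. The search is deterministic: a closed-form linear
#' least-squares solution in `RT ln(gamma)` space seeds a small fixed
#' multistart of Nelder-Mead refinements in gamma space.
#'
#' @param dataset an [sle_dataset()].
#' @param props assumed [melting_properties()] of the crystallizing component
#'   on the fitted branch.
#' @param n_terms number of polynomial coefficients to fit, 1 to 3.
#' @param branch which branch to fit (default 1, the salt/HBA branch; the
#'   convention of the screening workflow).
#' @return An object of class `"rk_fit"`: `coeffs` ([rk_coefficients()]),
#'   `objective` (the gamma-space OF), `aad` (K, of the re-predicted liquidus
#'   against the data; `NA` if any re-prediction is infeasible), `n_points`,
#'   `feasible`.
#' @export
fit_rk_coefficients <- function(dataset, props, n_terms = 1L, branch = 1L) {
  stopifnot(inherits(props, "melting_properties"))
  n_terms <- as.integer(n_terms)
  if (n_terms < 1L || n_terms > 3L) stop_domain("`n_terms` must be 1, 2 or 3")
  pts <- branch_points(dataset, branch)
  if (nrow(pts) < n_terms)
    stop_fit(sprintf("need at least %d interior branch-%d points, got %d",
                     n_terms, branch, nrow(pts)))
  x <- pts$x
  xj <- 1 - x
  T_exp <- pts$T_K
  gamma_exp <- gamma_from_sle_point(x, T_exp, props)
  rt_lng <- GAS_CONSTANT * T_exp * log(gamma_exp)
  seed <- rk_linear_seed(xj, rt_lng, n_terms)
  of <- function(cf) {
    g_cal <- exp(rk_polynomial(xj, cf) / (GAS_CONSTANT * T_exp))
    sum((g_cal - gamma_exp)^2)
  }
  starts <- list(seed, 0.5 * seed, 1.5 * seed, rep(0, n_terms))
  best <- NULL
  for (st in starts) {
    res <- if (n_terms == 1L) {
      half_width <- 2e5 + 3 * abs(st[1])
      stats::optim(st, of, method = "Brent",
                   lower = -half_width, upper = half_width,
                   control = list(maxit = 10000))
    } else {
      stats::optim(st, of, method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 10000))
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (!is.finite(best$value))
    stop_fit("Redlich-Kister objective did not evaluate to a finite value")
  cf <- rk_coefficients(as.numeric(best$par))
  T_calc <- liquidus_temperature(x, props, cf, infeasible_na = TRUE)
  feasible <- all(is.finite(T_calc))
  aad <- if (feasible) compute_aad(T_calc, T_exp) else NA_real_
  structure(
    list(coeffs = cf, objective = best$value, aad = aad,
         n_points = nrow(pts), n_terms = n_terms, branch = branch,
         props = props, feasible = feasible),
    class = "rk_fit"
  )
}

#' @export
print.rk_fit <- function(x, ...) {
  cat(sprintf(
    "Redlich-Kister fit (branch %d, %d term%s, n = %d):\n  coeffs (J/mol): %s\n  OF = %.10g, AAD = %.10g K%s\n",
    x$branch, x$n_terms, if (x$n_terms > 1) "s" else "", x$n_points,
    paste(sprintf("%.10g", x$coeffs$coeffs), collapse = ", "),
    x$objective, x$aad,
    if (x$feasible) "" else " [infeasible re-prediction]"))
  invisible(x)
}

#' Screen assumed melting enthalpies against SLE data
#'
#' For a component whose melting enthalpy is uncertain (e.g. it decomposes
#' before melting), re-derives the experimental activity coefficients under
#' each assumed enthalpy (a pure reference-state shift), refits the
#' Redlich-Kister polynomial, and records the fit objective, the liquidus
#' AAD, and the fitted activity coefficient of Component 1 at a stated
#' eutectic composition. Low assumed enthalpies make the component look
#' quasi-ideal (`gamma` near 1); high ones shift the apparent activity
#' coefficients away from unity; very low ones cannot reproduce the liquidus
#' shape and show up as large AAD.
#'
#' @param dataset an [sle_dataset()] with branch-1 points.
#' @param Tm_fixed melting temperature held fixed during the screening, K.
#' @param dHm_grid assumed melting enthalpies, J/mol (> 0).
#' @param n_terms Redlich-Kister terms per fit (1 to 3).
#' @param x_eutectic Component-1 mole fraction at which the fitted
#'   `gamma_1` is reported (typically the experimental eutectic composition).
#' @param T_eutectic temperature at which that `gamma_1` is evaluated; by
#'   default the fitted model's own liquidus temperature at `x_eutectic`.
#' @return A data frame of class `"screening_table"` with one row per
#'   assumed enthalpy: `dHm_Jmol`, coefficient columns `a`, `b`, `c`
#'   (`NA` beyond `n_terms`), `OF`, `AAD_K`, `gamma_at_xe`, `feasible`.
#'   Infeasible assumptions are flagged, never dropped.
#' @export
screen_melting_enthalpy <- function(dataset, Tm_fixed, dHm_grid,
                                    n_terms = 2L, x_eutectic,
                                    T_eutectic = NULL) {
  if (length(dHm_grid) == 0L) stop_domain("`dHm_grid` must be non-empty")
  if (any(!is.finite(dHm_grid)) || any(dHm_grid <= 0))
    stop_domain("`dHm_grid` entries must be positive enthalpies in J/mol")
  if (!is.numeric(x_eutectic) || length(x_eutectic) != 1L ||
      x_eutectic <= 0 || x_eutectic >= 1)
    stop_domain("`x_eutectic` must lie in (0, 1)")
  rows <- lapply(dHm_grid, function(dh) {
    props <- melting_properties(Tm_fixed, dh)
    fit <- tryCatch(fit_rk_coefficients(dataset, props, n_terms = n_terms),
                    slekit_error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(dHm_Jmol = dh, a = NA_real_, b = NA_real_, c = NA_real_,
                        OF = NA_real_, AAD_K = NA_real_,
                        gamma_at_xe = NA_real_, feasible = FALSE))
    }
    cf3 <- c(fit$coeffs$coeffs, rep(NA_real_, 3 - length(fit$coeffs$coeffs)))
    Te <- if (is.null(T_eutectic)) {
      liquidus_temperature(x_eutectic, props, fit$coeffs, infeasible_na = TRUE)
    } else T_eutectic
    g_e <- if (is.finite(Te)) {
      exp(rk_log_gamma(1 - x_eutectic, fit$coeffs, Te))
    } else NA_real_
    data.frame(dHm_Jmol = dh, a = cf3[1], b = cf3[2], c = cf3[3],
               OF = fit$objective, AAD_K = fit$aad, gamma_at_xe = g_e,
               feasible = fit$feasible && is.finite(g_e))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("screening_table", "data.frame")
  out
}
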