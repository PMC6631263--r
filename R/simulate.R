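#' Specification for a synthetic SLE dataset
#'
#' Describes how to generate liquidus observations with known ground truth:
#' a true [binary_system()], the number of points per branch, the sampled
#' composition range per branch, Gaussian noise on the measured temperature
#' (the quantity a DSC-style SLE experiment actually measures), and a
#' mandatory seed.
#'
#' Composition ranges default to the feasible stretch of each branch between
#' the system's eutectic and the pure end, with a margin of 0.02 mole
#' fraction away from the eutectic to avoid branch ambiguity.
#'
#' @param system the true [binary_system()].
#' @param n_per_branch points per branch (0 allowed on branch 2 for
#'   salt-solubility style data); at least one branch must have points.
#' @param sigma_T standard deviation of the temperature noise, K (>= 0).
#' @param seed integer seed; required so every dataset is reproducible.
#' @param x1_range_branch1 range of Component-1 mole fraction sampled on
#'   branch 1 (default `c(x1_e + 0.02, 0.99)`).
#' @param x1_range_branch2 range sampled on branch 2 (default
#'   `c(0.01, x1_e - 0.02)`).
#' @return An object of class `"generator_spec"`.
#' @export
generator_spec <- function(system, n_per_branch = 20L, sigma_T = 0,
                           seed, x1_range_branch1 = NULL,
                           x1_range_branch2 = NULL) {
  stopifnot(inherits(system, "binary_system"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_domain("`seed` is mandatory and must be a single integer")
  n_per_branch <- rep_len(as.integer(n_per_branch), 2L)
  if (any(n_per_branch < 0L) || sum(n_per_branch) < 1L)
    stop_domain("`n_per_branch` must be non-negative with at least one point overall")
  if (!is.numeric(sigma_T) || length(sigma_T) != 1L || sigma_T < 0)
    stop_domain("`sigma_T` must be a non-negative noise level in K")
  structure(
    list(system = system, n_per_branch = n_per_branch, sigma_T = sigma_T,
         seed = as.integer(seed),
         x1_range_branch1 = x1_range_branch1,
         x1_range_branch2 = x1_range_branch2),
    class = "generator_spec"
  )
}

#' Generate a synthetic SLE dataset
#'
#' Samples compositions uniformly on each branch's configured range,
#' evaluates the true liquidus temperature from the system's melting
#' properties and Redlich-Kister coefficients, adds Gaussian temperature
#' noise, and returns an [sle_dataset()] whose provenance records the seed
#' and noise level. The same spec always yields the identical table. With
#' `sigma_T = 0` every generated point satisfies the liquidus equation to
#' numerical precision.
#'
#' @param spec a [generator_spec()].
#' @return An [sle_dataset()]; the true system is attached as attribute
#'   `"truth"`.
#' @examples
#' sys <- binary_system(
#'   melting_properties(600, walden_enthalpy(600)),
#'   melting_properties(300, walden_enthalpy(300)))
#' d <- simulate_sle_dataset(generator_spec(sys, 10, sigma_T = 0.5, seed = 42))
#' @export
simulate_sle_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  sys <- spec$system
  margin <- 0.02
  need_ep <- (spec$n_per_branch[1] > 0L && is.null(spec$x1_range_branch1)) ||
    (spec$n_per_branch[2] > 0L && is.null(spec$x1_range_branch2))
  ep <- if (need_ep) eutectic_point(sys) else NULL
  r1 <- spec$x1_range_branch1 %||% c(min(ep$x1_e + margin, 0.99), 0.99)
  r2 <- spec$x1_range_branch2 %||% c(0.01, max(ep$x1_e - margin, 0.01))
  old_seed <- globalenv()$.Random.seed
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  pts <- list()
  if (spec$n_per_branch[1] > 0L) {
    x1 <- sort(stats::runif(spec$n_per_branch[1], r1[1], r1[2]))
    T1 <- liquidus_temperature(x1, sys$props1, sys$coeffs1, infeasible_na = TRUE)
    if (any(!is.finite(T1)))
      stop_no_liquidus(sprintf(
        "branch-1 forward model infeasible at x1 = %s",
        paste(signif(x1[!is.finite(T1)], 6), collapse = ", ")))
    pts$b1 <- data.frame(x1 = x1, T_K = T1, branch = 1L)
  }
  if (spec$n_per_branch[2] > 0L) {
    x1 <- sort(stats::runif(spec$n_per_branch[2], r2[1], r2[2]))
    T2 <- liquidus_temperature(1 - x1, sys$props2, sys$coeffs2, infeasible_na = TRUE)
    if (any(!is.finite(T2)))
      stop_no_liquidus(sprintf(
        "branch-2 forward model infeasible at x1 = %s",
        paste(signif(x1[!is.finite(T2)], 6), collapse = ", ")))
    pts$b2 <- data.frame(x1 = x1, T_K = T2, branch = 2L)
  }
  tab <- do.call(rbind, pts)
  if (spec$sigma_T > 0)
    tab$T_K <- tab$T_K + stats::rnorm(nrow(tab), 0, spec$sigma_T)
  rownames(tab) <- NULL
  out <- sle_dataset(tab, name1 = sys$name1, name2 = sys$name2,
                     provenance = sprintf(
                       "synthetic: seed = %d, sigma_T = %g K, n = %d + %d",
                       spec$seed, spec$sigma_T,
                       spec$n_per_branch[1], spec$n_per_branch[2]))
  attr(out, "truth") <- sys
  out
}

#' Generate a shared-component family of SLE datasets
#'
#' Emulates the salt-solubility layout in which one component (e.g. a
#' quaternary ammonium salt) is paired with several partners: every dataset
#' shares Component 1's true melting properties, while each partner brings
#' its own melting properties and its own branch-1 Redlich-Kister
#' coefficients. With all-ideal coefficients and no noise, the pooled
#' ideal-solubility regression recovers the shared melting properties
#' exactly; heterogeneous non-ideality makes the per-system fits scatter
#' around (and bias away from) the truth.
#'
#' @param shared_props [melting_properties()] of the shared Component 1.
#' @param partners list of partners, each a list with elements `props`
#'   ([melting_properties()]), optional `coeffs1` (branch-1
#'   [rk_coefficients()], default ideal) and optional `name`.
#' @param n_per_branch,sigma_T,seed generator defaults applied to every
#'   partner (each partner p uses sub-seed `seed + p - 1`).
#' @param x1_range_branch1 branch-1 composition range shared by the family
#'   (default per-system feasible range, see [generator_spec()]).
#' @return A list of [sle_dataset()] objects, one per partner.
#' @export
simulate_shared_component_family <- function(shared_props, partners,
                                             n_per_branch = 20L,
                                             sigma_T = 0, seed,
                                             x1_range_branch1 = NULL) {
  stopifnot(inherits(shared_props, "melting_properties"))
  if (!is.list(partners) || length(partners) < 1L)
    stop_domain("`partners` must be a non-empty list")
  if (missing(seed)) stop_domain("`seed` is mandatory")
  out <- lapply(seq_along(partners), function(p) {
    pt <- partners[[p]]
    sys <- binary_system(
      shared_props, pt$props,
      coeffs1 = rk_coefficients(pt$coeffs1 %||% numeric(0)),
      name1 = "shared",
      name2 = pt$name %||% sprintf("partner %d", p))
    spec <- generator_spec(sys, n_per_branch = c(n_per_branch, 0L),
                           sigma_T = sigma_T, seed = seed + p - 1L,
                           x1_range_branch1 = x1_range_branch1)
    simulate_sle_dataset(spec)
  })
  names(out) <- vapply(out, function(d) attr(d, "name2"), character(1))
  out
}
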