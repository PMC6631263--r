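---
title: "Modeling solid-liquid equilibria and eutectic points with slekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling solid-liquid equilibria and eutectic points with slekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slekit)
```

## The thermodynamic model

A simple binary eutectic system has two liquidus branches, one per
crystallizing component. Along branch *i* the solid of pure component *i*
coexists with the liquid mixture, and equality of chemical potentials gives

$$\ln\left(x_i \gamma_i\right)
  = -\frac{\Delta h_{m,i}}{R T}\left(1 - \frac{T}{T_{m,i}}\right)
    - \frac{\Delta c_{P,i}}{R}\left(1 - \frac{T_{m,i}}{T}
    + \ln\frac{T_{m,i}}{T}\right),$$

where $x_i$ and $\gamma_i$ are the liquid mole fraction and activity
coefficient of the crystallizing component, $T_{m,i}$ and $\Delta h_{m,i}$
its melting temperature and enthalpy, and $\Delta c_{P,i}$ the heat-capacity
difference between the subcooled liquid and the solid. The activity
coefficient refers to the subcooled-liquid reference state — which is why
the *assumed melting properties* and the *inferred non-ideality* are not
independent: shifting $\Delta h_m$ shifts every "experimental"
$\gamma$ by an exact, closed-form reference-state factor
(`gamma_from_sle_point()` and the identity tested in the suite).

The model assumes complete solid immiscibility (each solid crystallizes
pure), no solid-solid transitions, and a single simple eutectic geometry.
$\Delta c_P$ is rarely known and typically negligible next to the enthalpy
term, so `dCp = 0` is the default; the full equation remains available via
`liquidus_temperature_full()`.

Non-ideality uses the Redlich-Kister polynomial in the *other* component's
mole fraction $x_j$:

$$R T \ln\gamma_i = a^{(i)} x_j^2 + b^{(i)} x_j^3 + c^{(i)} x_j^4 .$$

It is flexible, has no physical content, and — because $RT\ln\gamma$ is
temperature-independent — makes the simplified liquidus *linear in T*:

$$T = \frac{\Delta h_m + P(x_j)}{\Delta h_m / T_m - R \ln x}.$$

The closed form is used whenever `dCp = 0`; with `dCp != 0` the residual is
solved by bracketed root finding. Each branch carries its own independent
coefficient set (Gibbs-Duhem consistency between the two empirical branch
fits is deliberately not enforced; the polynomial is used as a per-branch
correlation, not as a mixture $g^E$ model).

## Parameters and defaults

| Parameter | Units | Default | Why |
|---|---|---|---|
| `Tm` | K | — | pure-component melting temperature |
| `dHm` | J/mol | — | melting enthalpy; or derived as `dSm * Tm` |
| `dSm` | J/(mol K) | 54.4 (`walden`), 20.0 (`low`) | Walden rule for ordered crystals of rigid molecules; the low value represents disordered crystals |
| `dCp` | J/(mol K) | 0 | rarely measurable below the melting point; the correction term is small next to the enthalpy term |
| `a, b, c` | J/mol | none (ideal) | Redlich-Kister energies; the DES screening regime is `a <= 0` (negative deviation). Screened range −30000..0 J/mol |
| `n_scan` | — | 2001 | eutectic scan density (see below) |
| `sigma_T` | K | 0 | generator noise on the measured liquidus temperature |

All internal units are SI (J, mol, K). The command-line layer and the YAML
config reader accept kJ/mol and convert on read, since melting enthalpies
and Redlich-Kister energies are conventionally quoted in kJ/mol. Positive
Redlich-Kister entries (positive deviation) are accepted by the engine but
flagged with a warning: they raise the liquidus and are outside the DES
design space this package targets.

## Locating the eutectic

The eutectic is defined operationally as the minimum of the upper envelope
$\max(T_1(x), T_2(x))$, equivalently the intersection $T_1 = T_2$. The
solver scans a 2001-point composition grid, *log-dense toward both pure
ends* (down to $10^{-6}$ mole fraction), because the ideal eutectic of a
dissimilar pair sits extremely close to the low-melting side — for the
600 K / 300 K Walden pair it is at $x_1 \approx 1.4\times10^{-3}$, which a
uniform grid would straddle poorly. Every sign change of
$D(x)=T_1(x)-T_2(x)$ between feasible scan points is refined by bisection
to machine precision in $x$ (far tighter than the 1e-8 K the downstream
invariants need; it also makes the solution exactly invariant under
temperature scaling, since the scan grid lives in composition space).
If several intersections exist — possible when strong coefficients make a
branch non-monotonic — the lowest-temperature one is returned with a
warning. If the branches share no feasible composition, a typed
`slekit_no_eutectic_error` is raised.

A strongly negative polynomial can drive the closed-form numerator
$\Delta h_m + P(x_j)$ to zero or below; there is then no physical liquidus
at that composition. This surfaces as a typed `slekit_no_liquidus_error`
(or an explicit `NA` + feasibility flag inside curves, sweeps and the
screening table — infeasible nodes are recorded, never dropped).

Depression at the eutectic is reported normalized to the low-melting
component, $(T_{m,2} - T_e)/T_{m,2}$: at fixed melting *entropies* this
quantity (and the eutectic composition) is invariant under a common scaling
of both melting temperatures, so it isolates the parameters that actually
matter. The property suite asserts this invariance at $\lambda \in
\{0.1, 1, 10\}$ to 1e-9.

## Fitting and screening

`fit_ideal_melting_properties()` is ordinary least squares of $\ln x_1$ on
$1/T$: under the ideal model the slope is $-\Delta h_m/R$ and the intercept
$\Delta h_m/(R T_m)$. Pooled mode concatenates a shared-component family of
binaries; per-system mode fits each partner separately — the scatter
between per-system estimates is itself diagnostic of hidden non-ideality.

`fit_rk_coefficients()` minimizes the activity-coefficient objective
exactly as conventionally printed,

$$OF = \sum\left(\gamma_1^{cal} - \gamma_1^{exp}\right)^2,$$

in $\gamma$ space (not $\ln\gamma$ space). The search is deterministic:
because $RT\ln\gamma$ is linear in the coefficients, a closed-form linear
least-squares solution in that space seeds the optimizer, plus three fixed
additional starts (0.5x, 1.5x, zero); one-coefficient fits use Brent's
method on an interval, multi-coefficient fits Nelder-Mead with relative
tolerance 1e-12 and at most 10 000 evaluations. Only branch-1 points enter
the objective by default, matching the screening convention for
salt/HBA-rich data (branch 2 can be fitted by passing `branch = 2`). The
reported AAD, $\frac{1}{N}\sum|T^{cal}_i - T^{exp}_i|$, re-predicts the
liquidus from the fitted coefficients.

`screen_melting_enthalpy()` holds $T_m$ fixed (its back-fitted estimates
scatter far less than the enthalpy's), walks a grid of assumed
$\Delta h_m$, refits the polynomial at each value, and records OF, AAD and
the fitted $\gamma_1$ at a stated eutectic composition. The pattern this
produces on a fixture generated *ideally* at 5 kJ/mol: $\gamma \approx 1$
and near-zero OF at the generating value; $\gamma$ drifting far from unity
as the assumed enthalpy grows (pure reference-state shift); AAD largest for
grossly under-estimated enthalpies (1 kJ/mol), which cannot reproduce the
liquidus curvature at any coefficients.

One caveat the synthetic fixture exposes: with a grossly *over*-estimated
enthalpy (40 kJ/mol) and data extending toward the pure high-melting side,
the experimental $\gamma$ values span several decades, and the
$\gamma$-space objective concentrates its absolute error on the
exponentially small ones — whose inverse map back to temperature is stiff —
so the re-predicted AAD grows there too. Real salt-solubility datasets do
not probe that regime (the salts decompose before melting, capping the
accessible temperature range), which is why screening real data shows low
AAD across moderate-to-high assumed enthalpies while the wide-span
synthetic fixture does not. Tests assert the "highest AAD at the lowest
enthalpy" property on grids up to 20 kJ/mol and the qualitative
$\gamma$-pattern on the full 1-40 kJ/mol span.

## The synthetic-data generator

`simulate_sle_dataset()` samples compositions uniformly on each branch's
feasible range (by default from 0.02 mole fraction beyond the system's own
eutectic to 0.01 short of the pure end — the margin avoids ambiguity about
which solid crystallizes), evaluates the exact forward model, and adds
Gaussian noise to the *temperature*, since liquidus temperatures are the
measured quantity in DSC-style SLE experiments. Seeds are mandatory and
echoed into the dataset's provenance string; the same spec always
regenerates the identical table. `simulate_shared_component_family()`
builds the salt-with-several-partners layout (sub-seed `seed + p - 1` per
partner) used to exercise pooled vs per-system melting-property regression.

What the generator emulates: two liquidus branches with known melting
properties and known per-branch coefficients, homoscedastic temperature
noise, families sharing one component. What it does not emulate: composition
uncertainty, heteroscedastic or systematic (calibration, heating-rate) DSC
errors, metastable or polymorphic solids, solid solubility, and data
truncation at decomposition temperatures. Passing recovery tests on this
generator therefore demonstrates correctness of the estimation machinery
under the stated error model, not robustness to every artifact of real
calorimetry.

Default study conditions used across the tests: the hypothetical
600 K / 300 K pair with enthalpies from either the Walden rule
(32 640 / 16 320 J/mol) or the low-entropy convention (12 000 / 6 000
J/mol); one-parameter coefficient grids {0, −6, −12, −18, −24, −30} kJ/mol
per branch; a melting-temperature ratio grid 1 to 3 in steps of 0.25; noise
0.5 K with 15-20 points per branch; 200 replicates for the noisy-recovery
checks; a 597 K / 5 kJ/mol choline-chloride-like fixture for screening.
These sizes keep the full suite under a minute on one core while leaving
every monotone ordering with a comfortable margin.

## Numerical choices and degenerate inputs

- Gas constant 8.314462618 J/(mol K); `dCp` is liquid minus solid.
- Closed-form liquidus wherever `dCp = 0`; otherwise the residual is
  scanned downward from $T_m$ (400 steps) and the first sign change is
  refined by `uniroot` to 1e-8 K. The scan matters: a large `dCp`
  correction can bend the residual back so that the endpoints of
  $(1\,\mathrm{K}, T_m]$ do not bracket, with the physical root the one
  nearest $T_m$.
- `x = 1` returns $T_m$ exactly on every path; `x = 0`, non-positive
  temperatures, and out-of-range mole fractions raise
  `slekit_domain_error`.
- Exactly two regression points give the interpolating line with
  $R^2 = 1$; fewer raise a typed fit error, as does a zero intercept
  (which would put $T_m$ at infinity).
- A single-point one-coefficient fit interpolates exactly (OF = 0).
- Sweeps contain no randomness and reproduce bit-for-bit from their
  configuration; grid nodes violating the `Tm1 >= Tm2` labeling convention
  are flagged infeasible rather than silently swapped.

## Known limitations

Peritectics, congruently melting compounds, solid solutions and ternary
systems are out of scope, as are temperature-dependent Redlich-Kister
coefficients and predictive activity-coefficient models (Wilson, NRTL,
UNIFAC, PC-SAFT); the polynomial here is a correlation tool, chosen for
flexibility, not a recommendation. The screening workflow deliberately
cannot tell *which* assumed melting enthalpy is true — that is its point:
it quantifies how strongly the conclusion about liquid-phase interactions
depends on a quantity that is often unmeasurable.
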