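---
title: "Steady-state thermodynamics of unicyclic enzyme schemes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state thermodynamics of unicyclic enzyme schemes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycledissip)
```

## The model

Many well-characterized enzymes operate through a single productive
catalytic cycle: the free enzyme E binds substrate, passes through one or
two intermediate conformations (ES, EZ, EP), releases product, and returns
to E. `cycledissip` represents such a mechanism as a `cycle_scheme`: `N`
states (2-4 in the curated kinetic literature; any `N >= 2` is supported)
on a single loop, with every transition reversible and first-order. States
are numbered counterclockwise; edge `i` joins states `i` and `i + 1`
(mod `N`), with forward constants the odd-indexed microscopic constants
`k1, k3, k5, k7` and reverse constants `k2, k4, k6, k8` (s^-1).
Ligand-binding steps are pseudo-first-order: for E + S -> ES the stored
rate is `k1 = k1* [S]`, with `k1*` the second-order constant
(M^-1 s^-1). Declaring which edge binds substrate (edge 1, forward) and
which rebinds product (edge `N`, reverse) is what makes the
`[S] -> Inf / 0` and `[P] -> 0` limits - and hence kcat and kcat/KM -
well defined.

The stationary state of the master equation `dp/dt = W p = 0` exists and
is unique for any strictly positive rate set. At that state the cycle
carries one-way completion fluxes `J+ = prod(k_fwd)/Sigma` and
`J- = prod(k_rev)/Sigma`, where `Sigma` is the King-Altman sum of directed
spanning trees; the net flux is `J = J+ - J-` per enzyme. The driving
affinity is

```
X / RT = ln( prod k_fwd / prod k_rev ) = ln( K_eq / Gamma ),
```

with `Gamma = [P]/[S]` the mass-action ratio, and the total entropy
production over RT is the bilinear product `J * X / RT` (s^-1 per enzyme).
We adopt the convention that `X > 0` means net forward (substrate-consuming)
drive, i.e. `Gamma < K_eq` implies `X > 0`; this is the sign under which
`J+ >= J-` exactly when `X >= 0`. Note the alternative convention
`X = RT ln(Gamma/K_eq)` circulates in the literature; it flips the sign and
is *not* what this package reports.

Each bidirectional transition contributes a nonnegative *partial entropy
production*

```
sigma_i / RT = (k_fwd,i p_i - k_rev,i p_{i+1}) * ln( k_fwd,i p_i / (k_rev,i p_{i+1}) ),
```

and around a single cycle the log-ratios telescope, so the partial
contributions sum *exactly* to `J X / RT`. This conservation is a
structural identity and is property-tested to 1e-9 relative over a
thousand random schemes (observed worst case is ~1e-14). The equivalent
transition-matrix form `(W_ij p_j - W_ji p_i) ln(W_ij p_j / (W_ji p_i))`,
with `W_ij` the rate *from* `j` *to* `i`, gives the same numbers after the
index mapping; the tests check this explicitly.

### Catalytic parameters from microscopic constants

`kcat` is defined operationally as the `[S] -> Inf`, `[P] -> 0` limit of
`J`, and `kcat/KM` as the `[S] -> 0`, `[P] -> 0` slope of `J` versus
`[S]`. Because the King-Altman denominator is multilinear in every rate
constant, both limits have exact closed expressions; for 2- and 3-state
cycles they reduce to the familiar

```
kcat(2) = k3                      kcat/KM(2) = k1* k3 / (k2 + k3)
kcat(3) = k5 / (1 + k4/k3 + k5/k3)
kcat/KM(3) = k1* k3 k5 / (k2 k4 + k2 k5 + k3 k5)
```

For the 4-state cycle the same limit yields

```
kcat(4) = k3 k5 k7 / (k5 k7 + k4 k6 + k4 k7 + k3 k7 + k3 k6 + k3 k5)
        = k3 / (1 + k3/k7 + (k3/k5)(1 + 1/K2)(1 + (k5/k7)/K3)),
```

with step equilibrium constants `K2 = k3/k4`, `K3 = k5/k6`. We derived
this form directly from the saturating-flux limit and only then registered
the factored variant as a cross-check; the two routes (closed form vs
exact limit through the diagram algebra) agree to ~1e-15 and are enforced
at 1e-6 in the acceptance tests. Dimensional analysis fixes `kcat/KM` as a
second-order constant: the substrate concentration appearing in composite
rates is always divided out through `k1* = k1/[S]`.

`KM` is reported as the ratio `kcat / (kcat/KM)`. A scheme driven backward
(`X < 0`) keeps meaningful forward-defined kcat and KM; it is flagged
(`backward_driven`), not rejected.

### Dissipation at working concentrations

Dissipation is reported at the declared working concentrations. At
literally zero product the force - and with it `J * X` - diverges, so a
strictly-zero-`[P]` dissipation is not a finite quantity; what the limits
use is `[P] -> 0` *inside* `kcat` and `kcat/KM` only. Users who want the
dissipation at a different operating point rescale the binding edges with
`at_concentrations()` and re-solve. All dissipation values are reported as
dissipation/(RT) in s^-1 per enzyme (natural logarithms throughout the
thermodynamics; base-10 only in the scaling fits), which sidesteps the
per-molecule (`k_B`) versus per-mole (`R`) bookkeeping entirely.

## Numerical choices

* **Stationary distribution.** `solve_steady_state()` evaluates the
  directed-spanning-tree (King-Altman/Hill diagram) weights: sums of
  products of positive rate constants, hence no cancellation even when
  constants span ten orders of magnitude and probabilities reach 1e-30.
  A dense LU solve of the same system loses the small components
  (worst-case flux error ~0.4 on hard random schemes); it is therefore
  *not* the production route, but dense linear algebra (an eigenvector
  solve, and the subtraction-free GTH elimination) serves as the
  independent oracle in the test suite.
* **Degenerate 0·ln 0.** An edge whose one-way fluxes balance to within
  1e-14 relative contributes exactly 0 to the entropy production (the
  `x ln x -> 0` limit), and a cycle whose force satisfies
  `|X/RT| < 1e-12` is treated as exactly at equilibrium: `J`, `X`,
  dissipation, and every edge sigma are returned as literal zeros. The
  thresholds absorb the rounding of `sum(log(k))` while sitting far below
  any physically meaningful force.
* **Flux accuracy.** `J` is computed as `J+ - J-` from log-sum products,
  and the closed 2-/3-/4-state forms are kept as documented special cases
  cross-checked to 1e-9 relative (observed ~1e-13).

## The partial-EP maximizer

`mpep_optimize_edge()` maximizes one edge's partial entropy production
over that edge's *forward* constant, everything else fixed - so the step
equilibrium constant moves freely. Two behaviors occur:

* In the default mode, a bare unicyclic scheme typically shows a
  *monotone* rise of `sigma_edge(k)` to a plateau: as `k` grows the edge's
  occupancy `p_i` falls like `1/k`, the one-way flux saturates, and the
  edge log-ratio tends to a finite positive constant. The maximum then
  sits at the upper search bound and is flagged `boundary = TRUE` - never
  silently reported as interior.
* With `hold_step_equilibrium = TRUE` the reverse constant co-varies to
  keep the step equilibrium constant fixed. Then `sigma_edge` vanishes at
  both extremes (a rate-limiting edge carries no flux; a fast edge reaches
  local equilibrium and carries no force) and a genuine interior trade-off
  maximum exists.

Unimodality is never assumed: a coarse log-spaced grid (400 points)
brackets the global maximum before golden-section refinement on
`log10 k` (stopping width 1e-8 in relative `k`; sigma tolerance well below
1e-8 relative). The optimizer is deterministic and, in both modes, is
tested against a two-stage brute-force grid (1e4 coarse points, 1e3-point
refinement) to 1e-4 relative in `k`. Default bounds `1e-6..1e12 s^-1`
cover the physically plausible elementary-step range and are always
overridable. The two-edge variant alternates single-edge maximizations
until both optima move < 1e-6 relative (at most 100 sweeps; non-convergence
is reported in the result, never raised). Whether a simultaneous 2D search
would find a different fixed point is checked indirectly: the tests verify
order-invariance of the pair and stability of the fixed point under ±1%
perturbations.

## Ensemble scaling fits

Across a compilation of enzymes spanning many orders of magnitude,
dissipation/(RT) follows power laws in the catalytic parameters,
`diss/RT = 10^a * x^b` with `x = kcat/KM` or `x = kcat`.
`fit_power_law()` runs OLS on `log10` scales with dissipation as the
response - matching how the law is written - and reports the slope SE and
95% CI from the t distribution with `n - 2` df. Because neither variable
is error-free, a reduced-major-axis mode is exposed for sensitivity
analysis; on strongly correlated data the two agree closely. Rows with
nonpositive values or backward drive are excluded with a logged reason
(the scaling is defined for forward-driven enzymes; an equilibrium row has
zero dissipation and no log).

The two slopes share the same response on the same enzymes, so comparing
them with independent-SE z statistics would be invalid;
`compare_slopes()` uses a paired case-resampling bootstrap (seeded,
reproducible) and declares significance when the percentile CI of
`b_kcat - b_kcat/KM` excludes zero. `fit_plane()` fits the least-squares
plane in `(log10 kcat, log10 KM, log10 diss/RT)` space and reports the
residual SD as the plane-thickness statistic.

## What the synthetic generator emulates - and what it does not

`ensemble_spec()` / `generate_ensemble()` emulate the two statistical
features that dominate curated single-cycle rate-constant compilations:

* microscopic constants log-uniform over `10^-2..10^8 s^-1` (default),
  reflecting the well-documented many-decade spread of elementary-step
  rates;
* a strictly positive thermodynamic force on every enzyme, imposed by
  rescaling a *single* reverse constant so `X/RT` hits a target drawn
  uniformly from `[1, 40]` - one surgical change that leaves every other
  marginal untouched and is rejection-free.

Scheme sizes are drawn uniformly from `{2, 3, 4}`; working concentrations
default to a typical millimolar substrate (`[S] = 1e-3 M`) and micromolar
product (`[P] = 1e-6 M`), with the second-order binding constants
back-derived so all invariants hold by construction.
`generate_scaling_ensemble()` additionally imposes a power law with
log-normal scatter for calibrating the fitting pipeline (the default
calibration uses `n = 75`, slope 0.72, scatter SD 0.5 in log10 units, the
regime in which the OLS CI covers the truth in >= 93% of replicates).

The generator does **not** emulate enzyme-family structure, phylogenetic
correlation between class labels and kinetics, or the empirical joint
distribution of kcat and KM; class labels in the scaling ensemble are
uniform random. Passing tests on synthetic ensembles therefore validates
the *algebra and statistics* of the pipeline - conservation, oracle
equivalence, limit equivalence, optimizer correctness, CI calibration -
not any biological claim about real enzyme compilations, which require the
corresponding curated rate-constant table as input
(`read_enzyme_table()` accepts the documented CSV schema).

## Problem sizes and runtime

The shipped checks use 1000 random schemes for the conservation and
oracle-equivalence properties, 300 schemes for the concentration-limit
equivalence, 50 schemes against the 1e4-point optimizer grid (plus 10 in
the constrained mode), and 100 replicates of the 75-enzyme scaling
calibration; together they run in about two minutes on one CPU. All
randomness flows from explicit seeds.

## Known limitations

* Single cycles only: no multi-cycle diagrams, no strictly irreversible
  steps (a zero rate constant is a validation error; use a small positive
  value to approximate one), no light-driven or free-energy-transducing
  machines.
* Steady state only: no pre-steady-state (transient) kinetics.
* The CSV reader assumes the schema documented in `read_enzyme_table()`;
  tables in other layouts must be mapped to it first.
* Evolutionary distances are consumed as a plain numeric annotation
  column; sequence alignment and tree inference are external concerns.
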