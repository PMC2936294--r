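---
title: "Validating a small constraint-based model of Pichia pastoris with possibilistic flux analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a small constraint-based model of Pichia pastoris with possibilistic flux analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(possMFA)
```

## The problem

Extracellular rates are often the only measurements available for a
bioprocess: substrate uptake, growth, ethanol formation, and the two gas
rates (OUR, CPR). A small stoichiometric model of central carbon metabolism
can turn those few numbers into statements about the cell's internal state —
but only if the model itself deserves trust. This package implements a
quantitative validation workflow for such models, exercised on a
44-reaction network of *Pichia pastoris* growing on glucose, glycerol
and/or methanol:

1. **Elementary flux modes**: enumerate every support-minimal steady-state
   route, classify it by substrate use and products, and compare maximal
   biomass yields against experimental ones.
2. **Consistency degrees**: quantify, per dataset, how much measurement
   error must be assumed before model and data agree — as a
   variance-weighted least-squares residual φ and as a possibilistic degree
   π.
3. **Prediction**: drop the measured growth rate, re-estimate it from the
   remaining rates, and check that the measurement falls inside the
   possibilistic interval.
4. **Rejection**: feed the model random rate combinations and confirm it
   rejects almost all of them — consistency with genuine data means little
   if the model accepts anything.

## The constraint-based model

At pseudo-steady state the internal metabolites cannot accumulate, so the
flux vector $v \in \mathbb{R}^{44}$ obeys

$$N v = 0, \qquad D v \ge 0,$$

where $N$ is the stoichiometric matrix over the 36 balanced internal
metabolites and $D$ selects the 27 irreversible reactions. No kinetics, no
objective function: the model is the *set* of flux states satisfying these
constraints.

The shipped network (`pichia_model()`, transcribed in
`inst/extdata/pichia_ccm.tsv`) covers EMP glycolysis, the TCA cycle with a
glyoxylate shunt, the pentose phosphate pathway, the fermentative branch to
ethanol, methanol oxidation (alcohol oxidase, formaldehyde and formate
dehydrogenases) and assimilation (dihydroxyacetone synthase), and glycerol
uptake through glycerol 3-phosphate. Pyruvate, acetyl-CoA, oxaloacetate and
the redox cofactors are kept in separate cytosolic and mitochondrial pools.
Two modelling restrictions matter for everything downstream:

* **No energy cofactors.** ATP is not balanced. Consequently pyruvate
  carboxylase (an ATP-coupled carboxylation) is excluded; with a free
  carboxylation in the network, CO₂ refixation into oxaloacetate would let
  biomass yields exceed the carbon cap set by the biomass equation.
  Anaplerosis runs through the glyoxylate shunt instead.
* **Lumped biomass equation.** One reaction drains nine precursors
  (1.00 Cmol total carbon), NADPH and a nitrogen source per Cmol of dry
  weight. Its cytosolic NADPH coefficient (0.1136 mol/Cmol) was calibrated
  once so that the LP-maximal growth yield is 0.8215 Cmol/Cmol of substrate
  carbon on *each* substrate — reproducing the published maximal yields
  4.93 (glucose), 2.46 (glycerol) and 0.82 (methanol) Cmol DW mol⁻¹. The
  equality across substrates is not an accident: every substrate reaches
  glucose 6-phosphate carbon-neutrally, and NADPH is supplied by the
  oxidative pentose phosphate branch at ½ carbon per NADPH regardless of
  the feed.

```{r}
model <- pichia_model()
model
```

Because every reaction balances carbon *and* redox electrons exactly
(`carbon_balance_audit()` verifies the former), two linear relations — the
carbon balance and the degree-of-reduction balance — hold among the seven
measured exchange rates. The seven measurements therefore contribute only

```{r}
measurement_rank(model, model$exchange_map$quantity)
```

independent constraints to the 8-dimensional flux space: flux estimation
stays under-determined, which is precisely why interval estimates rather
than point estimates are the honest output.

## Elementary flux modes

`enumerate_ems()` splits reversible reactions into forward/backward pairs,
so the flux cone becomes pointed, and runs an incremental double-description
algorithm: rays are intersected with one balance hyperplane at a time, and
new rays are kept only when the combinatorial adjacency test (no third ray's
support inside the union of the pair's supports) certifies extremality.
Futile two-cycle artefacts of the splitting are removed and sign-duplicate
fully-reversible modes collapsed. The algorithm is exact; on networks with
at most seven reactions the test suite checks it against an independent
oracle that examines every support subset for a one-dimensional,
sign-feasible restricted nullspace.

Canonical scaling makes yields readable: each mode is scaled to a summed
substrate uptake of 1 mol (largest-coefficient scaling for substrate-free
modes); zero is declared below 10⁻⁹ after scaling, and ties in
maximum-yield look-ups break toward the lowest mode id.

```{r}
ems <- enumerate_ems(model)
ems
max_yield_per_category(ems)
```

The reconstructed network yields more modes than the 98 reported for the
original published matrix (which is not redistributable here); counts of
support-minimal routes are sensitive to exactly which parallel routes
(redox shuttles, bypasses) a transcription includes. The yield *values*
for single substrates are structural, not combinatorial, and match.

## Possibilistic measurement model

A measurement $w_m$ of the flux functional $v_m$ is relaxed as

$$w_m = v_m + \varepsilon_1 - \mu_1 + \varepsilon_2 - \mu_2,\qquad
  \varepsilon_1,\mu_1 \ge 0,\;
  0 \le \varepsilon_2 \le \varepsilon_2^{\max},\;
  0 \le \mu_2 \le \mu_2^{\max},$$

with linear cost $J = \sum \alpha\,\varepsilon_1 + \beta\,\mu_1$ and
possibility $\pi = e^{-J}$. The default shaping
(`shape_measurement()`) assigns full possibility to deviations within ±5 %
of the measured value and possibility 0.1 at ±20 %, hence
$\alpha = \beta = \ln(10) / (0.15\,s)$ with scale
$s = \max(|w_m|, \text{zero\_floor})$. A deviation of ±9.5 % then has
possibility ≈ 0.5. The natural logarithm is used throughout so that
$\pi = e^{-J}$ is self-consistent.

Zero-valued measurements (a glucose-free culture, an ethanol rate of 0)
would make the slope formula divide by zero; the `zero_floor` (default
0.05 mol kg⁻¹ h⁻¹) gives them a small but finite scale, keeping them as
genuine constraints — a measured zero ethanol rate *should* pin the
fermentative branch near zero.

Three LP-based quantities summarise a dataset
(`max_possibility()`, `minimal_full_band()`, `flux_interval()`):

* $\pi(v_{mp})$, the possibility of the best flux state — 1 means some
  steady state lies inside every ±5 % band;
* the smallest uniform relative band $b$ such that a steady state exists
  within $b\,s$ of every measurement (a solver-free consistency currency:
  no shaping parameters enter). Consistency tables conventionally print
  the *full width* of this band, $2b$, and `run_validation()` reports both;
* γ-level intervals for any flux: the range of values whose **conditional**
  possibility (relative to the most possible state, $J \le J_{\min} -
  \ln\gamma$) is at least γ. Conditional semantics are the default because
  they remain informative for datasets whose absolute possibility is below
  γ — exactly the interesting, partially inconsistent cases; absolute
  intervals ($J \le -\ln\gamma$, empty when $\gamma > \pi$) are available
  via `conditional = FALSE`.

```{r}
scen <- load_scenarios()
d1 <- scen[scen$id == "D1", ]
meas <- to_measurements(d1, model)
max_possibility(model, meas)$pi
minimal_full_band(model, meas)
```

## Weighted least-squares residual

`wls_residual()` minimises $(w - Cv)^\top F^{-1} (w - Cv)$ over the
constraint set, with $F$ diagonal from a 10 % relative standard deviation
(floored like the possibilistic scales, for comparability). The problem is
reduced to the 8-dimensional nullspace of $N$ and solved as a convex QP
(`quadprog`), with a ridge of relative size 10⁻⁸ on the directions the
measurements do not see. Because irreversibility constraints can be active
at the optimum, φ does not follow a χ² distribution; it is reported as a
raw index, and the χ² reference quantile is attached only when no
inequality is active.

## Synthetic data: what it emulates, what it does not

* `random_battery()` draws each measured rate independently and uniformly
  within bounds — battery 1 within 0–10 throughout (uninformative),
  battery 2 within physiologically plausible ranges for these cultures
  (growth 1.5–6 Cmol kg⁻¹ h⁻¹, uptakes up to the observed maxima, ethanol
  ≤ 0.1, OUR 2.1–7.2, CPR 1.5–4 mol kg⁻¹ h⁻¹). Independence across columns
  is the point: genuine metabolic states are strongly correlated, so a
  valid model should reject nearly all of these draws.
* `sample_feasible_flux()` draws Dirichlet-weighted nonnegative mixtures of
  elementary modes: exact steady states by construction (exactness over
  uniformity; the sampler makes no claim of covering the cone uniformly).
* `perturb_measurements()` multiplies each exchange rate by an independent
  uniform factor in $[1-\text{rel\_noise}, 1+\text{rel\_noise}]$ — white
  multiplicative noise, no autocorrelation, drift or instrument bias.

Passing the recovery and rejection tests therefore shows the machinery is
sound on idealised data; it does not certify the model against structured
real-world error.

## Numerical choices

* **Linear programs** are solved by a dense two-phase tableau simplex
  written for this package (tens of variables, tens of constraints), with
  Bland's rule switched on after a pivot budget to exclude cycling, a 10⁻⁹
  pivot tolerance, and a KKT/complementarity residual returned with every
  solution. It is validated against brute-force vertex enumeration on
  randomized problems in the test suite.
* **Rank** is computed from singular values with tolerance
  $\max(m,n)\,\varepsilon\,\sigma_{\max}$.
* **Mode zero threshold** 10⁻⁹ after canonical scaling; steady-state checks
  use 10⁻⁸.
* **Degenerate inputs**: empty scenario lists produce empty (not invalid)
  reports; substrate-free modes raise an explicit yield error; enumeration
  past the configured ray cap raises a resource error rather than
  truncating silently.

## Problem sizes

The shipped analyses run on: the 44-reaction network (167 modes, enumerated
in well under a second), 11 experimental datasets (7 measurements each;
all three consistency quantities per dataset in under a second), rejection
batteries of 500 random datasets each, and recovery simulations of 15–30
draws in the test suite. The full test suite and the acceptance script each
complete in a few minutes on one CPU.

## Known limitations

* The stoichiometric matrix is this package's own transcription of a
  simplified *P. pastoris* central-carbon network; elementary-mode
  *counts* and mixed-substrate yield maxima depend on transcription details
  (parallel redox routes, lumping choices) and differ from values reported
  for other encodings of the same biology. Single-substrate maximal
  yields, consistency degrees and rejection rates are robust to these
  details.
* No ATP/energy balance: yields are carbon/redox-limited only, and energy
  burdens (e.g. recombinant protein expression, maintenance) are invisible
  to the model — datasets from high-producing cultures show exactly the
  degraded consistency this predicts.
* Protein productivity (`q_p`) is carried in the datasets but not mapped
  onto the model by default (`include_qp` exists for extended models with a
  protein efflux).
* Possibilistic results are conditional on the chosen shaping (±5 %/±20 %,
  zero floor); the shaping is a modelling statement about measurement
  quality, not a fitted quantity.
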