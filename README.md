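# possMFA

Possibilistic metabolic flux analysis and elementary-mode tools for small
constraint-based models, with a bundled central-carbon model of the
methylotrophic yeast *Pichia pastoris*.

## What problem this solves

For most cultivations the only numbers available are extracellular rates:
substrate uptake (glucose, glycerol, methanol), growth, ethanol, and the
gas-exchange rates OUR and CPR. Classical metabolic flux analysis needs
enough measurements to determine the flux vector; with a handful of noisy
rates the system stays under-determined and MFA in the textbook sense is
impossible. This package takes the constraint-based route instead: the
model is the set of flux vectors `v` satisfying

```
N v = 0        (steady state of the internal metabolites)
D v >= 0       (irreversibility)
```

and every question is answered against that set —

- **Elementary flux modes**: all support-minimal steady-state routes, their
  macroreactions (net substrate → product conversions), and maximal
  biomass yields per substrate combination.
- **Consistency**: how much measurement error must be assumed before a
  dataset fits the model, quantified two ways: a variance-weighted
  least-squares residual φ, and a possibilistic degree π = e^(−J), where J
  is the minimal cost of the measurement deviations (full possibility
  within ±5 % of each measured value, π = 0.1 at ±20 %). Both are LP/QP
  computations, exact under the inequality constraints.
- **Interval estimation of non-measured fluxes**: the range of values of
  any flux with conditional possibility ≥ γ, from two LPs per flux —
  including leave-one-out prediction of the growth rate as a validation
  exercise.
- **Rejection tests**: batteries of random rate combinations that a
  trustworthy model must reject.

Intended users: anyone validating or exploiting small (tens of reactions)
stoichiometric models against scarce extracellular data — bioprocess
monitoring, model curation, teaching.

The bundled model (44 reactions, 45 compounds, 36 balanced metabolites,
8 degrees of freedom) covers glycolysis, TCA with glyoxylate shunt, pentose
phosphate pathway, fermentative branch, methanol oxidation/assimilation and
glycerol uptake, with compartmented cofactor pools and a lumped biomass
equation; eleven published culture datasets ship alongside it.

## Worked example

Dataset A3 is a culture growing on a glycerol/methanol mixture with
substantial recombinant-protein production:

```r
library(possMFA)
model <- pichia_model()
model
#> metabolic_model: 44 reactions, 45 compounds ( 36 internal ), 17 reversible
#> degrees of freedom: 8

ems <- enumerate_ems(model)
ems
#> em_set: 167 elementary modes; 42 without biomass formation; 17 producing ethanol
max_yield_per_category(ems)[c(1, 5, 7), ]
#>   substrates max_yield  mode
#> 1    glucose 4.9289411 em075
#> 5   glycerol 2.4644705 em022
#> 7   methanol 0.8214902 em101

scen <- load_scenarios()
a3   <- scen[scen$id == "A3", ]
meas <- to_measurements(a3, model)

max_possibility(model, meas)$pi          # 0.295
minimal_full_band(model, meas)           # 0.093
wls_residual(model, scenario_values(a3))$phi   # 2.47
```

Reading: the maximal theoretical yields (Cmol dry weight per mol substrate)
are 4.93 on glucose, 2.46 on glycerol, 0.82 on methanol — the experimental
yield of every dataset stays below its theoretical ceiling. For A3, the
best flux state has possibility 0.295: the data are only moderately
consistent with the model, and a uniform relative band of ±9.3 % around the
measurements (a full width of ≈ 19 %) is needed before some steady state
agrees with all of them — consistent with the elevated least-squares
residual φ = 2.47. High-producing cultures divert resources the model does
not represent, and the consistency indices surface exactly that.

Predicting the growth rate from the other six rates:

```r
est <- estimate_excluded_flux(model, meas, "biomass")
est$most_possible                        # 1.69
est$intervals
#>   gamma lower upper
#> 1   0.8  1.43  1.75
#> 2   0.5  1.24  1.87
#> 3   0.1  0.82  2.14
```

The measured growth rate (1.72 Cmol kg⁻¹ h⁻¹) falls inside even the
tightest (γ = 0.8) interval: the model predicts growth it never saw.

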