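---
title: "Ligand distribution among water, lipid bilayer and protein: model, bias correction and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand distribution among water, lipid bilayer and protein}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipaff)
```

## The problem

Binding assays for membrane proteins — and for water-soluble proteins
studied in lipid-containing media such as blood plasma — are usually
analysed as if the ligand were distributed only between the aqueous phase
and the protein.  When the medium also contains a lipid phase (liposomes,
detergent micelles, nanodiscs, native membranes, lipoproteins), a
lipophilic ligand partitions into it.  Ignoring that partition makes the
fitted binding constant an *apparent* quantity that depends on the lipid
volume fraction and on the ligand's lipophilicity; affinities measured in
different systems then cannot be compared, and structure-activity trends
can be artefacts of lipid partitioning rather than protein recognition.
lipaff implements the closed-form equilibrium treatment of this
three-compartment system for a protein with a single binding site, the
closed-form bias between apparent and intrinsic affinity, and the
machinery to correct literature values and to extract intrinsic constants
from titration data.

## The model

The ligand `L` distributes among three environments: free in water
(`L_W`), associated with the lipid bilayer (`L_Lb`, non-saturable
partition) and bound to the protein's single site (`L_P`, saturable
binding).  Two equilibria suffice to describe the system:

* partition, a ratio of **local** concentrations:
  `KP_Lb/W = c_Lb / c_W` (dimensionless);
* binding from water: `Keq_LW = [L_P] / ([P] [L_W])` (1/M).

The third equilibrium — binding from the bilayer — is not independent:
the three constants form a thermodynamic cycle, so micro-reversibility
imposes `KP_P/W = KP_Lb/W × KP_P/Lb` (`close_cycle()`), and a protein
partition coefficient converts to a molar binding constant through the
protein's molar volume, `Keq = KP × V̄_P` (`keq_from_partition()`).
Whether the ligand physically reaches the site from water or from the
bilayer does not change the equilibrium distribution, only which constant
is directly measurable.

Throughout the package, concentrations are **moles per litre of total
system volume** and partition coefficients are ratios of **local**
concentrations; every function documents which convention each argument
uses.  The composition of one assay condition is captured by
`system_composition()`: total ligand `LT`, total protein `PT`, bilayer
volume fraction `alpha_lb`, and the derived protein and water fractions
`alpha_p = PT × V̄_P` and `alpha_w = 1 − alpha_lb − alpha_p`.

### Dilute-regime solution

Mass balance (`LT = L_W + L_Lb + L_P`, `PT = P + L_P`) with
`L_Lb = L_W KP V_Lb / V_W` reduces to a quadratic in `L_W`:

```
Keq (1 + KP V_Lb/V_W) L_W² + [ (1 + KP V_Lb/V_W) − Keq (LT − PT) ] L_W − LT = 0
```

whose physically meaningful root is always the larger one (the product of
the roots is negative, so exactly one root is non-negative).
`solve_dilute()` implements it with the cancellation-safe formulation
(when the linear coefficient is positive the root is computed as
`−2c / (b + √(b² − 4ac))`), and handles `PT = 0` and `Keq = 0` as exact
linear special cases rather than through the quadratic.  The dilute form
is valid while water dominates the volume; the package warns when
`alpha_w < 0.99`, the stated validity bound.

### General (concentrated-media) solution

For arbitrary compositions the package closes the system with exact
volume bookkeeping: the **local** aqueous concentration `c_W = n_W / V_W`
drives both the lipid partition (`n_Lb = KP c_W V_Lb`) and the binding
step (`L_P / (P c_W) = Keq`).  With `A = alpha_w + KP alpha_lb` the mass
balance again reduces to a quadratic, now in `c_W`:

```
A Keq c_W² + [ A + Keq (PT − LT) ] c_W − LT = 0
```

`solve_general()` reduces to `solve_dilute()` within 0.1% whenever
`alpha_lb + alpha_p ≤ 0.01`, which is how the two routes cross-validate
each other in the test suite.  The general form captures the *exclusion
effect*: a polar ligand with `KP < 1` is concentrated into the shrinking
aqueous volume by added bilayer, so protein saturation — and the apparent
affinity — *increase* with lipid.

### Apparent-affinity bias

Fitting data from a lipid-containing system with the depletion-corrected
single-site model that ignores the bilayer yields an apparent constant
related to the intrinsic one by

```
KeqApp / Keq = 1 / (1 + KP alpha_lb)            (dilute)
KeqApp / Keq = 1 / (alpha_w + KP alpha_lb)      (general)
```

independent of protein concentration (`bias_dilute()`,
`bias_general()`).  In the general form the substitution
`L' = A c_W` shows the relation is *exact* for data generated by the
general model, which the fitting tests confirm.  The relation inverts to
recover intrinsic constants from reported apparent ones
(`intrinsic_from_apparent()`, `orders_of_decrease()`), and a series of
apparent constants measured at several lipid loads extrapolates to zero
lipid, recovering both `Keq` and `KP` (`extrapolate_to_zero_lipid()`).

The second, even cruder approximation — assuming the ligand in large
excess so the hyperbola `L_P = PT K LT / (1 + K LT)` applies
(`bound_excess_ligand()`) — produces a bias that additionally grows with
protein concentration and leaves visibly structured residuals; the
scenario tables quantify both behaviours.

## Tunable parameters

| parameter | unit | default | rationale |
|---|---|---|---|
| `specific_volume` | mL/g | 0.84 | reproduces the convention that 10 µM of a 50 kDa protein occupies volume fraction 4.2×10⁻⁴; protein partial specific volumes in the literature span roughly 0.70-0.85 mL/g (a serum-albumin figure of 3% v/v at 600 µM implies ≈0.76), so the value is user-overridable and deliberately not reconciled |
| `molecular_weight` | g/mol | 50 000 | a medium-size protein; every constructor accepts any value |
| dilute-warning threshold | — | `alpha_w < 0.99` | the stated validity bound of the dilute equations; a warning, not an error, since the quadratic remains solvable |
| `lt_range` (generator) | M | `0.01/Keq … 100/Keq` | four decades around the dissociation constant, the standard design for saturation titrations |
| `n_points` (generator) | — | 20 | typical titration length |
| `sigma` (generator) | saturation units | 0.02 | a typical absolute precision for optically detected binding assays |
| fit convergence | — | rss reltol 1e-14 + 1-D polish to ~1e-12 in log10 K | noiseless self-consistency tests require ≈1e-6 relative recovery |

Lipophilicity inputs: when only a computed octanol-water `CLogP` is
available, `KP = 10^CLogP` is used verbatim (the desk-check examples for
very lipophilic P-glycoprotein inhibitors are only consistent with
`CLogP`, not with the pH-corrected `CLogD`).  This is a documented
stopgap: octanol-water partition is an imperfect proxy for bilayer
partition, and a measured liposome partition coefficient should be
preferred whenever one exists.

## The synthetic-data generator

`generate_titration()` emulates a saturation binding titration: a
log-spaced total-ligand grid, the exact (`solve_general()`) saturation
curve, and additive Gaussian noise on the saturation fraction, clipped to
[0, 1], under a caller-supplied seed (the global RNG state is restored
afterwards, and a fixed seed gives byte-identical output).  It does *not*
emulate several features of real assays: signal calibration error
(noise is on the true saturation, not on a raw signal), heteroscedastic
or correlated noise, pipetting error on the ligand grid, ionization-state
changes of the ligand, or lipid effects on protein conformation.
Parameter-recovery results on these fixtures therefore demonstrate the
correctness and calibration of the estimation machinery, not robustness
to every real-world artefact.

## Numerical and design choices

* **Root selection and stability.**  Always the larger quadratic root;
  cancellation-safe branch on the sign of the linear coefficient; exact
  special cases for `PT = 0` / `Keq = 0`; tiny negative `L_P` from
  floating-point cancellation is clamped to zero.
* **Fit parameterisation.**  `fit_titration()` optimises `log10 K`
  (positivity for free), initialised from the half-saturation point of
  the data, with a 5-point log-spaced multistart spanning the
  concentration range as fallback and a final Brent polish.  Residuals
  are unweighted, on the observed response scale.  Standard errors come
  from a central-difference jacobian and the delta method; convergence is
  reported honestly (`converged`, `n_iter`) rather than silently.
* **Extrapolation to zero lipid.**  Fitted by Levenberg-Marquardt on
  log-scale residuals: errors on equilibrium constants are
  multiplicative, and along a lipid titration the apparent constants span
  orders of magnitude, so unweighted linear-scale residuals would let the
  few largest values dominate and understate the uncertainty of the
  extrapolated constant.  The reciprocal-linear route (regression of
  `1/KeqApp` on `alpha_lb`) supplies starting values and a cross-check
  only, because reciprocal transforms distort noise.  On noiseless series
  both routes agree to ≈1e-6 relative.
* **Scenario formalism.**  The water-soluble-protein scenario tables
  (`saturation_curves`, `apparent_vs_lipid`) are generated with the
  dilute formalism, matching their simulation conditions, so the
  zero-lipid column is exactly unbiased; the membrane-protein tables use
  the general solver/ratio throughout.  Grid densities are a package
  choice (default 50 points, configurable); physical parameters follow
  the documented study conditions.  In the dilute regime the bias ratio
  is independent of `LT`, so the lipid-titration bias column is reported
  once per composition even though saturation panels are computed at two
  ligand concentrations.
* **Problem sizes.**  Property tests run 200 random compositions per
  suite file and 1000 in the consolidated property block; parameter
  recovery uses 200 replicates of 20-point titrations — sizes at which
  the Monte-Carlo coverage estimate of a 3-standard-error interval is
  stable.

## Known limitations

* Single binding site only.  Multi-site or multi-occupancy pockets make
  the free-ligand equation polynomial of higher degree and the
  constant/coefficient correspondence occupancy-dependent; both are out
  of scope.
* Equilibrium only: no association/dissociation kinetics.
* The lipid bilayer enters only as a partition compartment; direct lipid
  effects on protein conformation are not modelled.
* No ionization-state (pH) modelling; a pH change that alters the
  ligand's bilayer partition must be represented by supplying a different
  `KP`.
* No temperature dependence or activity-coefficient corrections.
* Uncertainty propagation is first-order (delta method); no Bayesian or
  resampling intervals.
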