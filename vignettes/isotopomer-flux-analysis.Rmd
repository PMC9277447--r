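---
title: "Steady-state 13C-isotopomer flux analysis of the TCA cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady-state 13C-isotopomer flux analysis of the TCA cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcaflux)
```

## The labeling model

Cells fed [U-13C]glucose make uniformly labeled pyruvate through
glycolysis. Pyruvate enters the TCA cycle by two routes with distinct
isotopic fingerprints: oxidation through pyruvate dehydrogenase (PDH)
delivers a two-carbon acetyl unit whose carbons end up at glutamate C4-C5
on the first turn, while carboxylation through pyruvate carboxylase
(`y_pc`) builds a four-carbon oxaloacetate whose labeled carbons appear at
glutamate C2-C3. After several turns the label spreads over all five
glutamate carbons in a pattern that is a deterministic function of the
relative fluxes, and the fine structure (singlet/doublet/triplet/quartet)
of each 13C resonance reads out which adjacent carbons are labeled in the
same molecule. Lactate mirrors the cytosolic pyruvate pool: with a
uniformly labeled tracer, [1,2-13C2] and [2,3-13C2] lactate can only be
formed by pyruvate that has passed through the cycle and returned via
PEPCK and pyruvate kinase, so the lactate C2 doublets are the signature
of pyruvate cycling (`pk`).

`tcaflux` models seven lumped metabolite pools — pyruvate, lactate,
acetyl-CoA, oxaloacetate, 2-oxoglutarate/glutamate, a single symmetric
four-carbon pool spanning succinyl-CoA through malate, and PEP — each
carrying a probability distribution over its $2^n$ carbon-labeling
patterns. Every pool is a convex mixture of its inflows (mixture weights
are simple functions of the fluxes, all referenced to a citrate synthase
flux of 1), and each inflow maps source carbons to product carbons
according to the reaction's atom transitions. Fumarase scrambling is a
50:50 mixture of the identity and the end-to-end reversal applied where
the four-carbon pool becomes oxaloacetate. The free fluxes are:

| parameter | meaning | default bounds |
|---|---|---|
| `f_pdh` | fraction of acetyl-CoA turnover fed by pyruvate via PDH | [0, 1] |
| `y_pc`  | pyruvate carboxylase anaplerosis into oxaloacetate | [0, 5] |
| `pk`    | pyruvate cycling via PEPCK -> PEP -> pyruvate kinase | [0, `y_pc + y_s`] |
| `y_s`   | anaplerosis entering at succinyl-CoA | [0, 5] |

All are dimensionless, per turn of the cycle. The cataplerotic PEPCK
efflux that closes the oxaloacetate balance is `y_pc + y_s`, and cycling
cannot exceed it; the constraint is enforced by reparameterizing `pk` as
a fraction of that efflux, which keeps the optimizer's search box
rectangular. The pyruvate pool is closed by a glycolytic inflow constant
`g` (default 2.0 relative to citrate synthase), so the recycled fraction
of pyruvate is `pk / (g + pk)`; `g` is a modeling constant, not a fitted
quantity, and the lactate doublet fractions scale with it. Tracer
enrichment defaults to 1 (labeling in glucose-free medium, where
essentially all glycolytic pyruvate derives from the tracer); natural
abundance (1.1% per carbon) is off by default and available as a
post-hoc mixing step.

## Solving for the steady state, and its independent oracle

The steady state is the fixed point of the pool-mixing/atom-map update.
Because the update is a convex stochastic mixing map, synchronous
(Jacobi) iteration converges geometrically at a rate set by the
recycling fraction; the solver iterates to a total L1 change below
1e-10 (cap 10,000 iterations, typically ~100) with the per-column-sparse
transition matrices applied in compiled code. Two qualitatively
different implementations cross-validate each other: `steady_state()`
iterates distributions, while `sample_molecules()` synthesizes individual
molecules by stochastically back-tracing their biosynthetic lineage
through the same atom maps (choosing each inflow with probability equal
to its mixing weight) and never touches the matrix route. The test suite
requires the two to agree within three binomial standard errors per
labeling pattern at 20,000 molecules. Lineages are truncated at 1,000
recursive molecule visits; the truncation returns an unlabeled molecule
and its bias is bounded by the largest recycling weight raised to the
number of turns, which is negligible at that depth.

## From isotopomers to multiplets

A carbon's resonance splits according to which of its one-bond neighbors
are 13C in the same molecule. The multiplet area fractions are the
conditional probabilities of the neighbor-labeling states among molecules
labeled at the observed position, so they sum to 1 per resonance exactly
as line-fit areas normalized to the total resonance area do. Glutamate
C3 sees two nearly equal couplings (34 Hz to both neighbors), so its
two-neighbor state collapses to a 1:2:1 triplet and its one-neighbor
states merge into a single doublet; C2 and C4 have distinct couplings
and show resolved doublets and a quartet. The J values (glutamate
J12 = 53, J23 = J34 = 34, J45 = 51 Hz; lactate J12 = 55, J23 = 35 Hz)
are literature-typical constants and only matter for rendering spectra —
the fractions themselves are coupling-independent apart from the
collapse rule (tolerance 1 Hz). Only glutamate C2-C5 and lactate C2 are
emitted; C1 resonances are not quantified.

## The estimator and its observation model

`fit_fluxes()` minimizes the weighted squared difference between
observed and predicted multiplet ratios over the bounded flux box, using
bounded Levenberg-Marquardt (`minpack.lm`) from the conventional start
(PDH, PK, Y_PC, Ys) = (0.2, 0.3, 0.1, 0.2) plus nine reproducible
space-filling restarts (`lhs`), keeping the best objective (ties within
1e-10 resolve to the first found).

The estimator models the measurement, not just the chemistry. Fitted
multiplet areas cannot be negative: a component whose true area is
within about two standard deviations of zero is read out as a truncated
Gaussian with a small positive mean (`sigma * dnorm(0)` at zero area).
Ignoring this floor biases the cycling flux upward by roughly +0.03 at
the default noise — the floor on the lactate doublets masquerades as
cycling — and makes model comparison select the cycling model from pure
noise. The default `measurement_model = "truncated"` therefore fits the
expected measured ratio: a first pass fits the ideal model, the area
noise scale `sigma` is estimated (model-free from replicate scatter when
at least three replicates are present, otherwise from
variance-standardized residuals), and a second pass fits the
truncation-corrected prediction with each row weighted by its
observation-model precision. With noise-free data `sigma` is zero and
the correction vanishes, so exact recovery is untouched. Tables that
carry a `sem` column are weighted `1/sem^2` instead, as supplied.

Bootstrap intervals (`bootstrap_ci()`) resample residuals on the
variance-standardized area-error scale and push every pseudo-dataset
through the same observation model (clip at zero, renormalize per
resonance), which regenerates both the within-resonance error
correlation and the truncation behavior; intervals are normal-theory
from the bootstrap spread with a t quantile at the degrees of freedom
actually behind the noise scale (resonances x (replicates - 1) with
replicate structure). Simulation at the default conditions (noise sd
0.01, four replicates, 100 repetitions) puts the 95% interval coverage
of all four fluxes in the low-to-mid 90s — the package's recovery audit
(`analysis/05_recovery_study.R`) and the acceptance script recompute
this.

## Model comparison

`compare_models()` ranks variants (full; no cycling; no carboxylase) by
AICc in its Gaussian least-squares form. Two design choices matter.
First, with replicate samples the comparison runs on the
condition-averaged table: averaging four replicates makes each row's
error close to Gaussian (the AICc likelihood assumes normality, and the
zero-inflated truncated noise of near-zero components is far from it),
and the 17-row table keeps the small-sample AICc penalty meaningful.
Second, the noise scale behind the truncation floor is a shared nuisance
parameter: it is estimated model-free from replicate scatter at its
one-standard-error upper bound, so an underestimated floor cannot
masquerade as pathway flux — when the floor is uncertain, parsimony gets
the benefit of the doubt. In 100-repetition simulations at the default
noise this selects the cycling model essentially always when cycling is
present (pk = 0.3) and the reduced model about 9 times in 10 when it is
absent, close to the theoretical boundary-chi-square limit of an
AICc-type rule.

## The synthetic-data generator

`generate_dataset()` emulates the replicate structure of a cell-extract
NMR experiment: per-replicate true fluxes (optional lognormal
variability), noise-free model ratios, independent additive Gaussian
noise on every multiplet area (mimicking line-fit area error), clipping
at zero, and renormalization per resonance. Renormalization necessarily
shrinks the visible noise on dominant components (delta-method factor
`(1-x)^2 + x^2 (m-1)`), so the nominal `noise_sd` is only directly
visible on small-fraction components; the tests check it there. The
defaults — four replicates, noise sd 0.01, enrichment 1 — are the
conditions every simulation study in the package uses.

Preset conditions encode the qualitative biology of the study system:
loss of the MUL1 ubiquitin ligase raises pyruvate carboxylase
anaplerosis and pyruvate cycling; Akt2 or HIF-1alpha inhibition pulls
both back toward wild type; Akt2 loss suppresses cycling and
succinyl-CoA anaplerosis; HIF-1alpha activation partially restores them.
The numeric magnitudes are synthetic. They were sized by a power
calculation, not measurement: the per-sample cycling-flux estimate has a
standard deviation of 0.06-0.10 at the default noise, so orderings meant
to be detectable from four replicates need gaps of roughly three
standard errors of a group-mean difference (~0.2-0.3), and the preset
table in the README reflects that. What passing the end-to-end tests
shows is that the pipeline recovers contrasts of that size at this
noise level — not that real cells exhibit these magnitudes, and not that
smaller real differences would be detectable.

The generator does not simulate raw FIDs, phasing or baseline artifacts,
peak overlap between metabolites, natural-abundance background (unless
enabled), or compartment effects (cytosolic vs mitochondrial pyruvate);
conclusions about real spectra inherit those simplifications.

## The spectral front end

`render_spectrum()` draws a multiplet pattern as a sum of Lorentzian
lines (a doublet two lines split by J, a quartet four, a triplet three
at 1:2:1), and `fit_areas()` recovers component areas by non-negative
linear least squares with the line positions fixed — areas are the only
free parameters, with an optional one-dimensional linewidth refinement.
The default grid (12 ppm window, 16,384 points, 1 Hz linewidth at
150.9 MHz) keeps Lorentzian tails inside the window (<0.1% of area) and
samples each linewidth with ~9 points. Fully overlapping component line
patterns make the design singular and raise an explicit conditioning
error; couplings below the grid resolution are recorded as warnings in
the render result.

## Numerical choices and degenerate inputs

* Fixed point: L1 tolerance 1e-10, cap 10,000 iterations;
  non-convergence is an error carrying the last residual, never a
  silent result.
* A resonance with zero total signal (position never labeled) raises an
  explicit zero-area error rather than returning NaN fractions; inside
  the optimizer the continuous limit (singlet fraction 1) is used so the
  objective stays smooth near unlabeled corners.
* Invalid flux vectors (negative fluxes, `f_pdh` outside [0, 1],
  `pk > y_pc + y_s`) are rejected before any iteration.
* The generator redraws a resonance (bounded retries) if noise drives
  its total area to zero, then errors.
* All stochastic entry points (`sample_molecules`, `generate_dataset`,
  `fit_fluxes` restarts, `bootstrap_ci`) take explicit seeds and restore
  the caller's RNG state.

## Problem sizes

The shipped studies use the sizes that make their Monte Carlo error
small relative to the margins they check: 20,000 molecules for the
oracle comparison, 100 repetitions for recovery/coverage/selection
frequencies, 99 bootstrap resamples per interval, and 1,000 replicates
for the noise-honesty check. The analysis scripts under `analysis/` run
reduced versions (25-40 repetitions) for a quick audit.

## Known limitations

* Fluxes are relative (citrate synthase = 1); no absolute rates.
* Steady-state only: pre-steady-state labeling kinetics are out of
  scope, as are CO2 refixation and glutamine exchange beyond fast
  glutamate/2-oxoglutarate equilibration.
* `pk` is identified through the lactate C2 multiplets given the
  glycolytic inflow constant `g`; halving `g` roughly doubles the
  doublet signal per unit `pk`, so `pk` estimates are interpretable only
  relative to the declared `g`.
* The AICc comparison assumes the candidate set contains the true
  structure; it ranks parsimony, it does not validate the atom maps.
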