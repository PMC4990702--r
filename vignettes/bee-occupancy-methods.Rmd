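---
title: "Methods: dynamic occupancy models for wild-bee persistence under neonicotinoid exposure"
author: "beepersist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic occupancy models for wild-bee persistence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beepersist)
```

## The scientific problem

Opportunistic occurrence records collected by volunteer naturalists are
the only data source covering wild-bee communities at national scale
over decades. They carry no abundance information, effort varies
enormously between recorders, and non-detection is uninformative unless
the recording process is modelled. `beepersist` implements an analysis
pipeline for asking whether the persistence of wild-bee populations in
5 km grid cells is related to exposure to neonicotinoid seed treatments
on oilseed rape, while separating the ecological signal from the
observation process.

The package covers five stages, each usable on its own:

1. **FII index** — a pressure score for foliar-sprayed insecticides.
2. **Covariates** — the per-cell annual panel of oilseed-rape cover,
   neonicotinoid exposure and FII, from biennial survey data.
3. **Surveys** — converting raw occurrence records into a detection
   dataset with list-length effort categories.
4. **Model** — the multi-species dynamic Bayesian occupancy-detection
   model and its MCMC sampler.
5. **Posterior** — group-level effect summaries and counterfactual
   no-neonicotinoid projections.

A sixth module, the synthetic-data generator, produces complete study
inputs with known truth so that the whole pipeline can be validated
end to end without access to the national datasets.

## The model

Let $z_{i,j,t} \in \{0,1\}$ be the occupancy of species $i$ in 5 km
cell $j$ in year $t$. Occupancy follows a two-state Markov chain:

$$z_{i,j,t} \sim \mathrm{Bernoulli}\!\left(z_{i,j,t-1}\,\phi_{i,j,t} +
(1 - z_{i,j,t-1})\,\gamma_i\right),
\qquad z_{i,j,1} \sim \mathrm{Bernoulli}(\psi^0_i),$$

where $\gamma_i$ is a species-specific colonisation probability and
persistence is logit-linear in the previous year's centred covariates:

$$\mathrm{logit}\,\phi_{i,j,t} = \beta_{0i} + \beta_{1i}\,
\mathrm{OSR}_{j,t-1} + \beta_{2i}\,\mathrm{NEO}_{j,t-1} +
\beta_{3i}\,\mathrm{FII}_{j,t-1}.$$

A visit $k$ (a unique date x 1 km cell survey, pooled under its 5 km
cell) detects an occupying species with probability

$$\mathrm{logit}\,p_{i,k} = \beta_{4i} + \beta_{5i}\,\mathrm{short}_k +
\beta_{6i}\,\mathrm{long}_k + \alpha_{t(k)},$$

where short means a 2–3-species list and long a >3-species list; the
list length of a visit is an effort proxy, so *all* recorded species
count toward it, including species not retained for modelling. There
are no false positives: an absent species is never recorded.

Species-level parameters are exchangeable random effects. The
persistence covariate effects $\beta_{1i},\beta_{2i},\beta_{3i}$ are
drawn from *separate* normal hyper-distributions for oilseed-rape
foragers and non-foragers — the central contrast of the analysis —
while $\gamma$ (on the logit scale), $\beta_0$ and the detection
parameters each share one global hyper-distribution. The year effect
$\alpha_t$ is a shared (not species-specific) normal random effect;
predictions for "the average year" set $\alpha = 0$.

### Priors

"Uninformative" priors are operationalised as Normal(0, 10) on all
hyper-means, half-Cauchy(0, 2.5) (half-normal available) on all hyper
standard deviations, and Uniform(0, 1) on each first-year occupancy
probability $\psi^0_i$. All are overridable through
`occupancyPriors()`.

### Likelihood and sampler

The likelihood of a species' detection history at one site is computed
exactly by a two-state forward recursion that marginalises the latent
occupancy chain; years without visits contribute only transition
factors, which is how unsurveyed site-years are imputed. The recursion
(`siteLogLikelihood()`) is verified against an independent brute-force
enumeration over all $2^T$ occupancy paths
(`bruteForceLogLikelihood()`) to $10^{-10}$.

The default sampler (`fitOccupancyModel(..., sampler = "marginal")`)
is Metropolis-within-Gibbs on the marginal likelihood, implemented in
C++: adaptive random-walk updates for the nine species-level
parameters of every species and each year effect (adaptation of
proposal scales stops at the end of burn-in, keeping the kept draws a
valid Markov chain), conjugate Gibbs draws for hyper-means, and
log-scale random-walk updates for hyper-sds. Because persistence
probabilities only change when $\beta_{0..3}$ move, and detection
probabilities take one of 3 list classes x T years values per species,
both are cached and refreshed only for the parameter block being
proposed; this makes the full protocol practical on a single CPU.

A data-augmented variant (`sampler = "augmented"`) samples the latent
states explicitly by forward-filter backward-sampling and then updates
parameters conditional on them, mirroring the explicit-state BUGS
formulation of such models. It targets the identical posterior and is
kept as a slow cross-check for small instances; the test suite
compares the two samplers' posteriors on a tiny study.

Chains run sequentially with per-chain seeds derived deterministically
from the master seed; two runs with the same seed are bit-identical.
Convergence is monitored with the Gelman–Rubin statistic (`rhat()`,
floored at 1; a `split = TRUE` variant is available) on all
hyper-parameters plus five randomly chosen species-level parameters;
non-convergence is flagged on the fit object rather than raised as an
error. The reference protocol is 3 chains x 10,000 iterations with
5,000 burn-in and thinning 3; the package's own validation experiments
use a reduced protocol (3 x 2,000, burn-in 1,000, thinning 2) sized
for a single desk CPU.

## The FII index

Foliar insecticides (mostly pyrethroids) are scored with the bee
component of the Environmental Impact Quotient. Each active
ingredient's contribution in a region-year is
$3\,Z_{ai}\,P_{ai}\,(M_{ai,R}/A_R)$: $Z$ is the 5/3/1 toxicity class
from the contact LD50 (<1, 1–100, >100 µg/bee; the published brackets
are open so boundary values are assigned to the middle class, with an
`"outer"` option), $P$ the plant-surface half-life DT50/4 in days,
$M/A$ the application rate in kg/ha. The constant 3 is the EIQ
bee-exposure weighting, redundant here but retained for consistency
with the published quotient. Regional scores are summed over
ingredients, annualised by midpoint interpolation, and assigned to
each 5 km cell via the region holding the majority of its area
(supplied as a lookup table; the package does no polygon geometry).

## Covariates, units and centring

Biennial series (crop cover, proportion treated, FII) are annualised
with the midpoint rule (a missing interior year is the mean of its two
neighbours; larger gaps are an error, not silently bridged).
Neonicotinoid exposure is cover times the regional proportion treated,
both interpolated before the product. All three covariates are centred
on their grand mean over the modelled cell-years — centring scope is
the whole panel, not per-year or per-cell — and the means are stored
so that scenarios can be re-centred consistently. No standardisation
beyond centring is applied, so coefficient scales depend on the
declared input units (the synthetic study expresses cover as the
fraction of the 25 km² cell). The panel stores unlagged values; the
model applies the one-year lag, keeping a single source of truth.

## Counterfactual projections

`projectOccupancy()` propagates each posterior draw's expected
occupancy per site through the transition dynamics from the first
modelled year, starting at that draw's first-year occupancy (fitted
values; the projection does not re-condition on the observed
detections year by year). The `no_neonic` scenario zeroes the raw
exposure from the first treatment year (2002) onward and then
subtracts the *original* centring mean — the fitted coefficients are
defined against the original centring, so re-centring under the
scenario would silently shift every species' baseline. The percent
loss of extant grid cells is the relative difference of final-year
occupancy, evaluated within each posterior draw and averaged
(`method = "per_draw"`, the default) or on posterior means
(`method = "mean"`). Equal-tailed 95% intervals are used throughout.

## The synthetic study

`simulateBeeStudy()` generates all five input tables plus the true
parameters and states. Default conditions mirror the structure of the
national study at desk scale:

* 20 forager + 15 non-forager species, 150 five-km cells (25 one-km
  cells each) in 5 regions, years 1994–2011;
* biennial covariate tables (even years) to exercise interpolation;
* proportion of crop treated: 0 before 2002, then a logistic ramp
  from 37.4% (2002) to 83% (2011) with regional spread shrinking from
  0.08 to 0.05, the reported survey standard errors;
* oilseed-rape cover: per-cell base fraction Uniform(0.03, 0.8) with a
  gentle upward drift and lognormal observation noise;
* foliar usage tables spanning all three toxicity classes, giving FII
  scores of order 10–40;
* group-level truth set to the reported national posterior means
  (neonicotinoid: forager −1.37, non-forager −0.46; cover: 1.06,
  −0.09; FII: −0.017, −0.013), with hyper-sds 0.25 (0.02 for FII) —
  moderate interspecific heterogeneity chosen a priori, as the
  national analysis does not print them;
* persistence intercepts around logit⁻¹(1.4) ≈ 0.8, colonisation
  around 0.18, first-year occupancy Uniform(0.35, 0.8): occupancy
  levels informative enough that a desk-scale study identifies the
  persistence effects;
* volunteer effort: Poisson(12) visits per 5 km cell-year landing on
  random (1 km cell, date) slots; each visit draws a latent effort
  class (single/short/long propensities 0.51/0.24/0.25) that sets its
  detection covariates *before* detections are drawn, avoiding the
  circularity of conditioning effort on its own outcome. Detection
  intercepts around logit⁻¹(−4.3) ≈ 0.013 per single-list visit, with
  short/long lists raising the log-odds by ~1.2/~3.3 — casual single
  records rarely catch any given species; long lists are real surveys.

Each effort class targets a list length (single: 1, short: 2–3, long:
4 plus a Poisson excess), and background species — a pool of 150 rare
species standing in for the rest of the ~250-species fauna — fill
whatever the modelled detections leave open. This design carries two
assumptions the detection sub-model depends on, and both failed in
earlier drafts of the generator in instructive ways:

1. *Visit existence is exogenous.* Every visit records something (the
   background fill), so the presence of a survey in the records
   carries no information about the modelled species. If instead
   visits only existed when something was detected, apparent detection
   would be inflated exactly where occupancy is low and every
   covariate effect would be attenuated.
2. *The realised list category tracks the latent effort class.*
   Because background species fill to the target, a visit's category
   is promoted above its class only when modelled detections overflow
   the target, which the low single/short detection probabilities make
   rare. Without the fill, visits were promoted to higher effort
   categories exactly where many modelled species were present,
   again attenuating the covariate effects.

Background records also exercise the ≥500-survey inclusion filter
(all background species fall below it) and the rule that non-retained
species still count toward list length.

Under these defaults roughly half of realised surveys are
single-species lists, and 33–35 of the 35 modelled species clear the
500-survey filter on typical seeds; species-group truths are compared
against the retained members in validation.

What the generator does **not** emulate: bee phenology within years,
spatial autocorrelation of occupancy or recorder behaviour, range
structure, misidentification, and the endogeneity of real list
categories (in real data the category *is* the realised list length;
the generator's latent-class device is a deliberate approximation so
that the generative detection model matches the fitted one). Passing
recovery tests therefore shows the estimator is consistent under the
model's own assumptions at desk scale — not that the national
estimates are free of the biases these unmodelled features can cause.

## Numerical choices and degenerate inputs

* Forward recursions run in probability space with lazy rescaling
  (renormalising only when mass underflows), one log per site.
* Histories with likelihood zero (e.g. a detection with $p = 0$)
  return $-\infty$ rather than an error; the sampler treats them as
  rejected states.
* Species never detected at a site contribute through the marginal
  likelihood; a single modelled year uses only $\psi^0$ and detection.
* LD50/DT50 must be positive; zero or missing values name the
  offending ingredient. Cells without a region mapping, panel gaps,
  and interpolation gaps >2 years are hard errors — silent bridging
  of data holes is never attempted.
* Boundary LD50 values (exactly 1 or 100 µg/bee) take the middle
  toxicity class by default (`boundaries = "outer"` flips them
  outward).
* `rhat()` is floored at 1: values below 1 are finite-sample noise of
  the estimator, and exactly identical chains return exactly 1.

## Problem sizes used in validation

The packaged validation experiments are sized for a single CPU: the
parameter-recovery study uses the default synthetic scale above with
the reduced MCMC protocol (about 6–8 minutes); likelihood oracle
checks run 1,000 random tiny instances; sampler cross-validation uses
a handful of species and sites. These sizes are the package's own
choices for routine validation; nothing prevents running the full
reference protocol on larger simulations.

## Known limitations

* The analysis is correlational; the counterfactual is a model-based
  projection, not a causal estimate.
* Spatial autocorrelation between cells and phylogenetic covariance
  between species are not modelled.
* The forager/non-forager dichotomy inherits the qualitative foraging
  list it is based on.
* At desk scale the non-forager exposure hyper-mean (−0.46) is only
  weakly identified: its posterior SD is of the same order as the
  effect itself, so recovered values scatter around the truth
  accordingly (see the acceptance experiment).
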