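---
title: "Validating climate envelope models across time: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating climate envelope models across time: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cemval)
```

## The problem

Climate envelope models (CEMs) relate species occurrence to climate and are
routinely projected forward to anticipate range shifts. Whether such
projections deserve trust is an empirical question that can only be answered
by *temporal* validation: calibrate on an early period ($t_1$), then test
against independent occurrence data from a later period ($t_2$). `cemval`
implements a validation framework built around three competing treatments of
climate-driven range change:

* **dynamic** - the model is projected onto $t_2$ climate, so the envelope
  may both expand and contract;
* **static** - the $t_1$ envelope is used unchanged, a null model of no
  climate-driven change;
* **hybrid** - areas of expansion (outside the envelope at $t_1$, inside at
  $t_2$) are appended to the $t_1$ envelope, while contraction is *not*
  removed. This encodes the biological hypothesis that populations may
  persist, at least transiently, in areas of declining suitability (sink
  persistence), while newly suitable areas can be colonized.

Because the hybrid prediction map is exactly the set union of the other two,
its sensitivity can never fall below either of theirs and its specificity can
never exceed either of theirs, *provided* the three maps are scored against
the same test points with the same threshold. The package treats this
union-containment relation as an always-on invariant and the test suite
asserts it replicate by replicate.

## Data model and conventions

Climate enters as seven derived variables on a shared grid: annual
precipitation, precipitation of the driest and wettest month (mm), mean
annual temperature, temperature annual range, and the maximum and minimum
mean monthly temperature (deg C). They are derived from 12 monthly surfaces
per year (`derive_climate_variables()`), averaged over each five-year period
(`period_mean()`), and block-aggregated from the native resolution to the
survey-route scale (`aggregate_grid()`, default factor 10, i.e. ~4 km to
~40 km).

Grid conventions are fixed once and used everywhere: cell-center
registration, half-open cells $[left, right) \times [bottom, top)$ so that a
point on a shared edge resolves deterministically; row 1 of a value matrix
is the northernmost row (ESRI ASCII grid file order); the origin is the
grid's lower-left corner. ASCII grids are written with 6 significant digits,
which makes a write/read/write cycle byte-stable.

Missing data are handled asymmetrically, on purpose. `period_mean()` is
conservative: a cell missing in any year is missing in the period mean - a
bad year should not silently change a cell's climatology.
`aggregate_grid()` is permissive: a coarse cell is the mean of whatever
fine cells are present, so coastal cells stay usable; only an all-missing
block aggregates to missing.

Occurrences follow the survey-route model: a route is a single coordinate
pair; repeat observations within a five-year window collapse to one presence
(`collapse_presences()`); background ("pseudo-absence") routes are drawn
uniformly among routes where the focal species was never recorded
(`sample_background()`; other species' presences do not disqualify a
route). For the $t_2$ period the background is re-sampled independently
among routes unoccupied at $t_2$, mirroring the $t_1$ procedure; a
`reuse_t1_background` flag restores the alternative reading.

## Models

`cem()` fits the presence/background suitability model. Two backends
satisfy one contract - probabilities in $[0,1]$, deterministic under a fixed
seed and fixed data:

* `"rf"`: a random forest classifier (500 trees by default), probability of
  the presence class.
* `"maxent"`: a maximum-entropy-style density-ratio estimator implemented
  as ridge-penalized logistic regression on standardized linear and
  quadratic features, with the background rows as the environmental
  background. With Gaussian species responses the true log odds are
  quadratic in the covariates, so this feature set is well specified; the
  light ridge penalty ($\lambda = 10^{-3}$) keeps coefficients finite under
  complete separation. The penalty is fixed, not tuned, which mirrors the
  "default settings" stance toward the modelling algorithms: the package's
  contribution is the validation framework, not the learners.

## Thresholds

Continuous suitability becomes presence/absence by `probability >=
threshold`, uniformly everywhere. Two criteria are implemented, both
computed once per species x algorithm on $t_1$ calibration data only and
then applied unchanged to all three approaches:

* **maximum kappa** (`max_kappa_threshold()`): five replicate 75-25
  calibration splits, Cohen's kappa evaluated on the held-out quarter at
  every threshold on the closed grid $\{0.01, 0.02, \ldots, 0.99\}$, mean
  kappa per threshold across replicates, argmax with ties broken toward the
  smallest threshold. The tie-break makes the search stable under
  resampling noise; the grid search is oracle-tested against exhaustive
  enumeration.
* **prevalence** (`prevalence_threshold()`):
  $n_{presences} / (n_{presences} + n_{background})$.

When both criteria are configured, the one achieving the greater $t_2$
sensitivity is reported (`select_reported_threshold()`); an exact tie goes
to prevalence, whose lower threshold suits the sensitivity-oriented uses
the framework targets.

## Evaluation

`evaluate_species()` runs the resampled validation. The published
description of the resampling ("a 75-25% training-testing split on 100
random partitions of the occurrence data") is ambiguous about *which* data
are partitioned; the package resamples both ends: each replicate refits the
model on a stratified 75% subsample of the $t_1$ calibration matrix *and*
scores a stratified 25% subsample of the $t_2$ evaluation points. Both
fractions are independently configurable, so either single-ended reading
can be recovered by setting the other fraction's behaviour to cover all
data. Means and SDs over replicates use the $n-1$ denominator.

Threshold metrics (sensitivity, specificity, TSS) are computed from the
binarized maps; AUC is computed from continuous probabilities and is
threshold-free: `auc_dynamic` uses $t_2$-projected probabilities at the
test points, `auc_static` uses $t_1$-projected probabilities at the same
points. AUC uses the rank-sum definition (ties count one half), verified
against brute-force pair counting. One published wrinkle: the source text
describes TSS as ranging 0-1, but the standard statistic
$sensitivity + specificity - 1$ ranges $-1$ to $1$; the package implements
the standard formula.

The static-vs-dynamic AUC comparison (`static_exceeds_dynamic_auc()`) is a
strict inequality on means, evaluated per species across both algorithms.

## Diagnostics

`change_proportions()` locates each species' $t_2$ presences and absences
on the dynamic-approach range-change map (`classify_range_change()`:
expansion, contraction, stable suitable/unsuitable - a partition of the
grid). Two regressions connect per-species metric differences to those
proportions and to traits:

* hybrid-minus-dynamic sensitivity gain vs. niche breadth (number of land
  cover types), defaulting to the maximum-entropy models because their
  sensitivity is the greater;
* static-minus-dynamic specificity gain vs. log body mass (dispersal
  proxy), defaulting to random forest because its specificity is the
  greater.

`linear_regression()` is ordinary least squares with an $F$ test on
$(1, n-2)$ degrees of freedom; a perfect fit is reported with a flag and an
infinite $F$ rather than a spurious p-value. One caption/text conflict in
the source material (sensitivity differences plotted against expansion vs.
contraction proportions) is resolved in favour of the running text: the
sensitivity gain is regressed on the *contraction* proportion.

The packaged CSV fixtures carry the published per-species summary table
(12 species x 2 algorithms) and trait table; `reproduce_paper_tables()`
recomputes every statistic that is a pure function of those tables. Note
one internal inconsistency of the source tables: the running text reports a
mean hybrid specificity of 0.47, but the mean of the 24 printed per-species
values is 0.451; the package reports the honestly recomputed value
alongside the published reference.

## The virtual-species simulator

Real validation data cannot ship with the package, so the simulator
generates data with the statistical structure the analysis assumes, plus
ground truth. `climate_scenario()` builds two five-year periods of monthly
climate: a north-south annual-temperature gradient (16 deg C across the
domain), a seasonal cycle (amplitude 10 deg C), an east-west precipitation
gradient (800 mm/yr across the domain) with a wet/dry season, and cell-level
interannual noise (0.3 deg C, 5 mm monthly SD). The default between-period
deltas (+0.9 deg C, +5.2 mm annual precipitation applied uniformly) are
calibrated to the magnitudes of observed change between the two periods of
the motivating study system; the spatial pattern is synthetic.

A `virtual_species()` has Gaussian responses (product across variables,
scaled to 1 at the joint optimum), a true envelope at suitability >= 0.5,
and three mechanism dials: per-year detection probability (a route in an
occupied cell is missed only if undetected in all five years, probability
$(1-d)^5$ - the collapsing rule's analogue), persistence probability for
occupied cells that lose suitability, and a dispersal radius limiting
colonization of newly suitable cells.

`scenario_presets()` packages the contrasts of interest: `tracking`
(persistence 0, unlimited dispersal - dynamic should win), `no_shift`
(zero deltas *and* zero noise, so $t_1 = t_2$ exactly and dynamic equals
static cell for cell; the noise is zeroed to isolate the no-change limit),
`persistence` (persistence 0.9 with narrower thermal breadths, 0.9-1.8
deg C, so the 0.9 deg C warming produces real contraction zones),
`dispersal_limited` (radius 0, persistence 1: a fully inert range), and
`generalist_vs_specialist` (breadth and persistence co-varying). Presets
use a 60 x 60 grid, 600 routes and 12 species, with temperature optima
spread over 5-16 deg C so that per-species exposure to expansion and
contraction varies - that variation is what the gain-vs-proportion
regressions exploit. Background draws are 200 routes per species: the
published design's 1000 background points cannot exist among 600 routes,
so the simulator scales the background to the route pool while the
1000-point default remains in the user-facing functions.

What the simulator does *not* emulate: spatial autocorrelation of survey
effort, observer heterogeneity, non-climate drivers of occupancy (land
cover, biotic interactions), range dynamics beyond the
persistence/dispersal dials, and coordinate projection issues. Passing
scenario tests therefore demonstrates that the framework recovers the
mechanisms it parameterizes, not that any particular real dataset meets the
framework's assumptions.

## Orchestration, determinism and problem sizes

`run_study()` composes the whole pipeline behind a validated
`study_config()` (YAML-readable). Every stochastic component draws a named
sub-seed fanned out from one master seed (`fanout_seed()`), so a study is
reproducible end to end; the run manifest echoes the seeds and a config
hash, and repeated runs under one master seed are byte-identical. Stage
failures propagate with the stage name and species id attached.

Default problem sizes are chosen for desk-scale experimentation: 20
evaluation replicates (the published analysis used 100; the estimator is
the same, the SDs are modestly noisier), 200 random-forest trees in
simulation studies (500 remains the `cem()` default), and the 60 x 60 /
600-route grid above. All are ordinary config knobs.

## Known limitations

* The maximum-entropy backend is a penalized-logistic surrogate for the
  reference MaxEnt implementation; it satisfies the same
  presence/background contract but is not feature-for-feature identical.
* GeoTIFF input depends on the `tiff` package, which exposes pixel values
  but not georeferencing tags; geometry must be supplied by the caller.
  ESRI ASCII grid is the fully supported interchange format.
* The mixed-effects significance tests of the motivating study are out of
  scope by design; `replicates.csv` exports the per-replicate metric table
  such models would consume.
* Change-proportion regressions are reported as `NA` rows when a scenario
  produces no variation in the proportions (e.g. a no-change world), since
  the regression is undefined there.
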