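# cemval

Temporal validation of climate envelope models (CEMs).

Climate envelope models relate species occurrences to climate and are
widely projected into future climates to anticipate range shifts — but how
well do such projections classify *independent* occurrence data from a
later time period? `cemval` implements a validation framework that
calibrates presence/background suitability models on an early period
(*t₁*), evaluates them against survey occurrences from a later period
(*t₂*), and compares three treatments of climate-driven range change:

| approach | prediction map | assumption |
|---|---|---|
| dynamic | envelope projected onto *t₂* climate | envelope expands **and** contracts |
| static  | *t₁* envelope unchanged | no climate-driven change |
| hybrid  | *t₁* envelope ∪ areas of expansion | expansion happens, contraction does not (sink persistence) |

Because the hybrid map is the set union of the other two,
sens(hybrid) ≥ max(sens(dynamic), sens(static)) and
spec(hybrid) ≤ min(spec(dynamic), spec(static)) whenever the three maps are
scored against the same test points — an invariant the test suite asserts
replicate by replicate.

The framework covers the full pipeline:

* **Climate grids** — ESRI ASCII grid I/O, derivation of seven bioclimatic
  variables from monthly surfaces, multi-year period means, block
  aggregation (~4 km → ~40 km), point extraction with deterministic
  half-open cell conventions.
* **Occurrences** — collapsing repeat observations to single presences per
  survey route, seeded background sampling among unoccupied routes.
* **Models** — `cem()` fits a random forest or a maximum-entropy-style
  penalized-logistic model under one probability contract, with `predict`
  and `project_surface()` methods.
* **Thresholds** — maximum-kappa search over a closed 0.01-step grid on
  resampled calibration splits, or species prevalence
  `n/(n + background)`; the criterion with the greater *t₂* sensitivity is
  reported.
* **Validation** — resampled (75–25, *k* partitions) sensitivity,
  specificity, TSS = sens + spec − 1, and rank-sum AUC, with a dynamic and
  a static AUC variant; range expansion/contraction map algebra.
* **Diagnostics** — proportions of *t₂* points in change areas, OLS
  regressions of per-species metric gains on those proportions and on
  traits (niche breadth, log body mass).
* **Virtual species** — a simulator with known truth and mechanism dials
  (detection, persistence in contracting areas, dispersal limitation),
  plus named scenario presets; `run_study()` orchestrates everything
  reproducibly from one master seed.

## Worked example

A persistence scenario: 12 virtual species on a 60 × 60 grid, warming of
0.9 °C between periods, occupied cells that lose suitability persisting
with probability 0.9.

```r
library(cemval)

preset  <- scenario_presets("persistence", seed = 42)
climate <- make_climate(preset$scenario)
routes  <- simulate_routes(climate$t1, preset$n_routes, seed = 42)

sp  <- preset$species[[1]]
sim <- simulate_occurrences(sp, climate, routes,
                            n_background = preset$n_background, seed = sp$seed)
mat <- build_model_matrix(sim$t1$presence_routes, sim$t1$background_routes,
                          routes, climate$t1)
th  <- prevalence_threshold(sum(mat$label == "presence"), preset$n_background)
th
#> <threshold_spec> prevalence: 0.15612

evaluate_species(mat, sim$t2, routes, climate, algorithm = "rf",
                 threshold = th, n_partitions = 20, seed = 42, ntree = 200)
#> <cem_evaluation> vsp01 (rf), 20 replicates
#>   dynamic  sens 0.731+/-0.093  spec 0.972+/-0.020  TSS 0.703  AUCdyn 0.942  AUCstat 0.972
#>   static   sens 0.600+/-0.110  spec 0.985+/-0.014  TSS 0.585  AUCdyn 0.942  AUCstat 0.972
#>   hybrid   sens 0.981+/-0.029  spec 0.961+/-0.018  TSS 0.942  AUCdyn 0.942  AUCstat 0.972
```

Read: the species persists in areas the dynamic model writes off, so the
dynamic approach misses ~27% of *t₂* presences and the static approach
40%; appending expansion to the *t₁* envelope (hybrid) recovers nearly all
of them (sens 0.98) at a small specificity cost — exactly the trade-off
the framework is built to expose. `run_study(study_config(scenario =
"persistence"))` repeats this for all 12 species and both algorithms, then
regresses the per-species hybrid sensitivity gain on the proportion of
presences in contraction areas (slope > 0, p < 0.001 at these settings).

The package also ships the published 12-species evaluation and trait
tables as plain CSV fixtures and recomputes every statistic that is a pure
function of them:

```r
reproduce_paper_tables()
#> Summary statistics recomputed from the packaged per-species table
#>                 statistic computed reference
#>       rf_dynamic_auc_mean   0.8475     0.848
#>   maxent_dynamic_auc_mean   0.8681     0.868
#>               rf_tss_mean   0.5238     0.524
#>   hybrid_sensitivity_mean   0.9679     0.970
#>   hybrid_specificity_mean   0.4511     0.470
#>  static_auc_exceeds_count   9.0000     9.000
#>
#> Trait regressions (df = 1, 10)
#>                                        test f_statistic  p_value    slope reference_f
#>  sensitivity_gain_vs_niche_breadth (maxent)      17.982 0.001715  0.01008       17.98
#>            specificity_gain_vs_ln_mass (rf)       4.296 0.064996 -0.01605        4.30
```

(The 0.4511 vs 0.470 row is a genuine discrepancy between the published
running text and the published per-species table; the computed value is
the mean of the 24 printed table entries.)

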