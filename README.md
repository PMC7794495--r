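# owlfam

Delayed natal dispersal and family living in an urban/rural bird population:
simulation and analysis toolkit.

In some territorial, otherwise non-social birds, a first-year individual may
stay at its natal nest through the next breeding season instead of dispersing
to breed, turning the resident breeding pair into a *family unit* (pair plus
one or two extra adults). `owlfam` provides the full quantitative machinery
needed to study this phenomenon in a two-habitat (urban vs rural) population
of burrowing owls — and, because such field data are rarely shareable, a
seeded individual-based simulator that generates populations with the same
statistical structure, so every analysis is testable end to end.

The package is aimed at population ecologists working with
capture–mark–recapture data, spatial covariates and AICc-based multimodel
inference, and at anyone needing a compact, dependency-light R
implementation of these engines.

## What is inside

* **Synthetic populations** (`sim_config()`, `simulate_landscape()`,
  `simulate_breeding_seasons()`, `simulate_chicks()`,
  `simulate_attendance()`, `simulate_encounter_histories()`,
  `simulate_dispersal()`, `simulate_genotypes()`, `simulate_study()`):
  clustered urban and sparse rural nest landscapes, logistic family-unit
  occurrence driven by conspecific density and neighbourhood productivity,
  zero-inflated productivity, allometric chick morphometrics, monotone
  monthly natal-nest attendance, a two-age-class CJS resighting process, and
  Mendelian microsatellite genotypes with a per-allele error model.
* **Spatial conspecific indices** (`aggregation_index()`,
  `productivity_weighted_index()`, `residual_conspecific_productivity()`):
  the per-nest aggregation index `S_i = Σ_{j≠i} exp(−d_ij)` (distances in
  km), its productivity-weighted variant
  `P_i = Σ_{j≠i} prod_j · exp(−d_ij)`, and the OLS residual of `P` on `S`
  used as the neighbourhood-productivity covariate; plus the body-condition
  residual `log10(mass) − (1.45 + 0.37·log10(wing))`.
* **Model selection** (`fit_glm()`, `fit_random_intercept()`, `aicc()`,
  `build_model_set()`, `model_average()`): binomial / Poisson /
  negative-binomial / Gaussian (G)LMMs with optional zero inflation and
  random intercepts (via `glmmTMB`), AICc
  (`−2ℓ + 2k + 2k(k+1)/(n−k−1)`), ΔAICc, Akaike weights
  `w_i = exp(−Δ_i/2)/Σ_j exp(−Δ_j/2)`, and full-model (zero-substitution)
  averaging with unconditional confidence intervals.
* **Cormack–Jolly–Seber engine** (`cjs_loglik()`, `fit_cjs()`,
  `predict_cjs()`, `cjs_model_average()`, `m_array()`, `chisq_gof_p()`,
  `bootstrap_gof()`): an individual-level CJS likelihood with age classes
  (urban juvenile / rural juvenile / adult), additive time variation,
  fieldwork-effort effects on recapture, and individual covariates; the
  "never-seen-again" probability is computed by backward recursion, and
  goodness of fit comes from a chi-square tail utility plus a
  parametric-bootstrap deviance test.
* **Resampling** (`dispersal_permutation_test()`,
  `bootstrap_survival_comparison()`, `z_test()`): the randomisation test for
  natal dispersal distances of delayed dispersers against the pool of
  first-year dispersers, and the cohort-matched 200-dataset survival
  comparison with a Z-test.
* **Kinship** (`pair_likelihood()`, `ml_relationship()`,
  `parentage_lod()`, `assignment_confidence()`,
  `allele_frequencies_from_sample()`): likelihood-based relatedness
  classification over the IBD classes U/HS/FS/PO
  (`L = k0·P(g1)P(g2) + k1·P(g1)T(g2|g1) + k2·P(g1)[g1=g2]` per locus) and
  Cervus-style parentage LOD scores with simulated Delta confidence
  thresholds.
* **I/O** (`read_inp()`, `write_inp()`, `read_genepop()`,
  `write_genepop()`, CSV writers): MARK encounter-history and GenePop
  genotype formats.

## Worked example

Simulate a default study population (13 seasons, 200 urban and 250 rural
nests) and ask what drives family-unit formation:

```r
library(owlfam)
cfg   <- sim_config(seed = 1)
study <- simulate_study(cfg)

tapply(study$events$unit_type == "family", study$events$habitat, mean)
#>      rural      urban
#> 0.03384615 0.07461538
```

Family units appear in about 7.5% of urban and 3.4% of rural breeding
events — the configured 7%/3% urban excess. The occurrence analysis fits the
11-model binomial candidate set (habitat, conspecific density, neighbourhood
productivity, interactions, null; year as a random intercept) and
model-averages:

```r
rep1 <- run_family_unit_analysis(study$events)
rep1$model_sets$occurrence$table[1:4, c("model", "k", "AICc", "delta", "weight")]
#>                             model k    AICc     delta      weight
#>  habitat + productivity + density 5 2209.31  0.000000 4.91105e-01
#>  habitat * productivity + density 6 2210.20  0.885598 3.15405e-01
#>  habitat * density + productivity 6 2211.18  1.862864 1.93490e-01
#>                 habitat + density 4 2265.78 56.467066 2.68848e-13

rep1$averaged[rep1$averaged$term %in% c("density", "productivity"), ]
#>          term estimate ci_low ci_high
#>       density    0.290  0.176   0.404
#>  productivity    0.269  0.145   0.392
```

The generator's log-odds effects (0.30 per unit of aggregation index, 0.22
per unit of residual conspecific productivity) are recovered with confidence
intervals excluding zero: nests in denser, more productive neighbourhoods
are more likely to host a family unit. The other reports work the same way:
`run_attendance_analysis()`, `run_productivity_analyses()`,
`run_condition_analyses()`, `run_lrs_analysis()` and
`run_survival_analyses()` each return the corresponding published-style
model-set table plus averaged estimates.

## Documentation

The methods vignette (`vignettes/owl-family-living.Rmd`) describes the
generative model, the likelihoods, every tunable parameter with its default
and rationale, the numerical choices, and the limits of what synthetic-data
tests can show about field data.
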