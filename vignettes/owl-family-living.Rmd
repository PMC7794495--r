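---
title: "Methods: simulating and analysing delayed dispersal and family living"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing delayed dispersal and family living}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`owlfam` studies a rare life-history tactic in a territorial, non-social
owl: a first-year bird stays at its natal nest through the following
breeding season ("delayed dispersal"), so the nest is attended by the
breeding pair plus one or two extra adults — a *family unit*. The package
implements the full analysis chain such a study needs — spatial conspecific
covariates, binomial/count/Gaussian mixed models under AICc multimodel
inference, a Cormack–Jolly–Seber (CJS) survival engine, bespoke resampling
procedures, and microsatellite kinship likelihoods — together with a seeded
individual-based simulator that generates populations with the same
statistical structure. This vignette is the package's methods account: the
models, their assumptions, the defaults and why, the numerical choices, and
what the synthetic-data tests do and do not establish.

## 1. The generative model

All generators draw from one `sim_config()`. Defaults encode the study
conditions of the motivating system; each is a config field and can be
changed.

### Landscape

Urban nests follow a parent–child (Thomas-type) cluster process on a square
of side `extent_km` (default 20 km): cluster centres uniform, about 8 nests
per cluster, within-cluster scale `extent_km/20` (1 km). Rural nests form
much looser clusters (about 4 nests per centre, scale 2.5 km) over a square
of twice the linear extent, reflecting the large rural expanses surrounding
a city; the rural square is offset so the habitats are spatially disjoint.
No coordinates exist to copy, so the point process is a modelling choice;
it is tuned to one purpose: the conspecific aggregation index
`S_i = Σ_{j≠i} exp(−d_ij)` must be systematically higher and more variable
in town (means ≈ 4 vs ≈ 1, within-habitat spread of order 1), because that
density gradient is what the family-unit occurrence model feeds on.

### Family-unit occurrence

Each nest-year is a family unit with probability
`plogis(b0_habitat + 0.30·S_c + 0.22·P_resid_c)`, where `S_c` and
`P_resid_c` are the aggregation index and the residual neighbourhood
productivity *centred within habitat*, and the slopes (config
`density_effect`, `productivity_effect`) act per raw covariate unit — the
same scale on which the analysis reports them. The habitat intercepts are
not fixed constants: each season `b0` is solved numerically (1-d root find)
so that the *marginal* family-unit fraction equals `p_family_urban` (0.07)
or `p_family_rural` (0.03). Without this calibration the covariate spread
would inflate the marginal fraction above its target (Jensen's inequality);
with it, both the printed marginal frequencies and the printed slopes hold
simultaneously. Family units have one extra adult in 97% of cases and two
in 3%.

The neighbourhood-productivity index is built from *provisional*
productivity draws, before family status is assigned — conceptually the
previous season's information — because the realised productivity depends
on family status, which depends on the index. Final productivity is then
drawn zero-inflated Poisson: a structural-zero probability
(`zero_inflation_prob`, 0.10 — total failures, e.g. predation) mixed with a
Poisson whose log-mean is the habitat mean (urban 3.0, rural 2.7 fledglings;
ratio ≈ 0.10 on the log scale) plus `family_productivity_effect` (0.27) for
family units.

### Chicks, attendance, encounter histories

Wing length is Normal(162, 8) mm — the source system reports no
morphometric distributions, so this is an assumption (documented, not
load-bearing). Log10 body mass follows the allometric line
`1.45 + 0.37·log10(wing)` plus the family-unit condition shift
(`condition_family_effect`, 0.02) and Gaussian noise (`condition_sd`,
default 0.06 — about ±15% of body mass, chosen so that the condition
contrast is detectable at cohort sizes of a few thousand while the
condition–survival slope carries realistic information).

Monthly natal-nest attendance (January–July, months 1–7) has marginal
log-odds `intercept + slope·m + urban + interaction·m·urban` with defaults
2.0 / −0.73 / 1.37 / 0.16 (the three non-intercept terms are the system's
reported estimates; the intercept is chosen so nearly all fledglings are
present in January). Within a bird, presence is *monotone* — once gone,
gone for good — implemented by a single-uniform coupling against the
running minimum of the monthly probabilities. Whenever the monthly
probabilities decline in time (true at the defaults) the marginals follow
the logistic model exactly, so a plain binomial GLM recovers the generating
coefficients.

Encounter histories follow the standard CJS generative process: marking
occasions staggered uniformly over occasions `1..T−1`; the first interval
after marking is survived with the habitat-specific juvenile survival
(`phi_juv_urban` 0.29, `phi_juv_rural` 0.21), later intervals with adult
survival (`phi_adult` 0.71); both receive a logit shift of
`phi_condition_effect` (0.92) per unit of centred body condition and
`phi_family_effect` (default 0 — being born in a family unit does not, by
default, change survival). Detection uses `p_recapture_low` (0.3) in
low-effort years (the first two occasions by default) and
`p_recapture_high` (0.6) otherwise.

### Dispersal and genotypes

Delayed dispersers recruit essentially next door: distances uniform on
[0, 413] m (the observed range; only the range is constrained, the shape is
a stand-in). First-year dispersers draw from a heavier-tailed log-normal
(median 700 m). Only the ordering of the two distributions matters for the
tests.

Genotypes descend a user-supplied pedigree
(`simulate_family_pedigree()` builds family units: sire, dam, a delayer who
is the pair's prior-season offspring, and the current brood — optionally
sired by the delayer). Founders draw from Hardy–Weinberg at each of
`n_loci` (17) loci with `alleles_per_locus` (5) alleles (Dirichlet-style
random frequencies); offspring inherit one allele per parent. Each recorded
allele is then independently replaced by a random frequency-weighted allele
with probability `genotyping_error` (0.01) — the package's single
genotyping-error model, used consistently in simulation and likelihoods.

## 2. Spatial indices and body condition

Distances enter `exp(−d)` in kilometres by default. The unit is
consequential: at metre scale the kernel underflows for any realistic nest
spacing and the index degenerates to zero, so the kilometre is the only
scale on which it varies; a `distance_unit` flag exposes the choice. The
focal nest is excluded from both `S` and the productivity-weighted `P`
(weighting is multiplicative: neighbour productivity times the distance
kernel). When a `year` column is present the indices are computed within
season over the nests active that season. The residual conspecific
productivity is the OLS residual of `P` on `S` with intercept — it asks
whether neighbours are more productive than their density alone predicts —
and errors out if all `S` are equal (no regression is possible).
Coincident nests are allowed (`exp(0) = 1`).

Body condition is `log10(mass) − (1.45 + 0.37·log10(wing))`. Base-10
logarithms are an inference, not a given: with natural logs those printed
coefficients would imply ~28 g owls, with base 10 ~180 g — only the latter
is a plausible burrowing owl. The base is a field of
`condition_coefficients()` and `fit_condition_regression()` can recalibrate
the line on any cohort.

## 3. Model selection and averaging

`fit_glm()` is the single fitting surface: plain fixed-effect models go
through `stats::glm()` / `MASS::glm.nb()`; anything with random intercepts
or a zero-inflation component is fitted by Laplace-approximated ML in
`glmmTMB`. Conventions:

* `k` counts every estimated parameter: coefficients, dispersion (Gaussian
  sigma, negative-binomial theta), the zero-inflation intercept, and each
  random-intercept variance.
* `n` for AICc is the number of observations, also in mixed models — a
  documented convention (group counts are an alternative nobody agrees on).
* The zero-inflation component is intercept-only; the analyses never needed
  covariate-dependent inflation, and an all-zero response is handled as the
  exact degenerate limit (likelihood 1, count coefficients flagged
  unidentifiable) rather than left to a diverging optimiser.
* The negative binomial uses the mean/dispersion (`nbinom2`)
  parameterisation, dispersion counted in `k`.
* Random-intercept variances estimated at the 0 boundary break the observed
  information; `fit_glm()` then drops the offending term and collapses
  toward the fixed-effect fit (whose estimates it matches at the boundary).
  This mirrors field practice, where random terms are dropped for
  convergence.

`build_model_set()` computes AICc, ΔAICc and Akaike weights
(`exp(−Δ/2)`, normalised), ordering by AICc with ties broken by model name.
`model_average()` performs *full-model* averaging over the whole candidate
set by default: a term absent from a model contributes 0 with that model's
weight, and the unconditional variance is
`Σ w_i (var_i + (b_i − b̄)²)` with normal 95% intervals. Averaging over the
full set (rather than only Δ ≤ 2) is the default because published
model-averaging columns list terms from non-top models; a `delta_max`
argument restores the threshold behaviour.

## 4. The CJS engine

The likelihood is individual-based (not m-array-based), which is what makes
individual covariates such as body condition possible; `m_array()` is kept
for summaries and reporting. For individual `i` marked at `f` with last
detection at `l`, the contribution multiplies survival terms over intervals
`f..l−1`, detection/non-detection terms at occasions `f+1..l`, and the
absorbing "never seen again" probability `χ_l`, computed by the backward
recursion `χ_t = 1 − φ_t(1 − (1 − p_{t+1})χ_{t+1})`, `χ_T = 1`. The
recursion is evaluated on `n × T` matrices, so one likelihood evaluation is
a handful of vectorised operations regardless of cohort size.

Design structures are R formulas over derived variables: `ageclass`
(JuvU/JuvR/Ad — juvenile parameters apply only to the first interval after
marking), `time` (interval factor, additive on the logit scale; "additive
temporal variation among groups" is shared time deviations), `habitat`,
`family_unit`, `condition` (centred), plus indicator shorthands
`juvU`/`juvR`/`adult` so age-class-specific covariate slopes like
`~ ageclass + I(juvU*condition) + time` can be written directly. Recapture
formulas use `time`, `habitat` and `effort` — a two-level factor, low for
the first two occasions by default and configurable per occasion. Because
the exact combination of time and effort on recapture in the source
analyses is not printed, both structures are available; the shipped model
sets use effort-only.

Fitting is quasi-Newton (BFGS) on the logit scale from zero starts,
covariance from the numerically differentiated observed information
(pseudo-inverse if singular), delta-method CIs back-transformed to
probabilities. `|logit| > 10` flags boundary estimates. A fully
time-varying φ and p leaves the terminal φ·p product unidentifiable; the
fit carries a `confounded_terminal` flag, and survival summaries are taken
at reference (non-terminal) levels. Rank-deficient designs (for example a
constant-zero covariate) warn rather than stop: the extra parameter simply
carries no information, which is also the behaviour the invariant tests
assert. AICc for CJS models uses `n` = number of individuals.

Goodness of fit: `chisq_gof_p()` gives the chi-square upper tail for an
externally computed overall statistic, and `bootstrap_gof()` is a
parametric bootstrap of the deviance under the fitted model (simulate with
the same marking occasions and covariates, refit, compare deviances; also
reports the dispersion ratio ĉ). The classical contingency-table component
decomposition of CJS residual tests is deliberately out of scope; the
bootstrap answers the same question — is the data more heterogeneous than
the model allows? — within this package's machinery.

## 5. Resampling procedures

`dispersal_permutation_test()` draws group-sized subsets *without
replacement* from the pooled non-philopatric distances ("shuffling" implies
permuting observed values, not resampling them), takes the group median as
the statistic (the reported group summary is a median; a mean variant sits
behind a flag), and computes `p = count(null ≤ observed)/n_iter` — the
plain denominator, matching "divided by 1000"; a `+1` correction is
available. One caveat the calibration tests made visible: with a small pool
the subset-median distribution under-disperses relative to a fresh sample's
median, and rejection runs above nominal (≈ 0.08 at pool 60); at the
study's sizes (pool ≈ 200, group ≈ 14) calibration is nominal
(0.05 ± 0.02). This is a property of the shuffling design itself, inherited
faithfully.

`bootstrap_survival_comparison()` keeps the (small) delayed group fixed and
draws `n_datasets` (200) cohort-matched control sets from the
non-philopatric pool, fitting a constant-φ, constant-p CJS model per group
per dataset. Because the delayed group is identical across datasets, its
mean and CI come from its single fit (delta method); the control side
reports the across-dataset mean and percentile CI; and `z_test()` combines
the delayed fit's SE with the across-dataset spread — one-tailed by
default, the only convention consistent with a printed (z, p) pair of
(0.76, 0.22).

## 6. Kinship likelihoods

Pairwise relatedness uses the IBD-coefficient mixture over four classes —
U (1,0,0), HS (0.5,0.5,0), FS (0.25,0.5,0.25), PO (0,1,0) — with per-locus
likelihood `k0·P(g1)P(g2) + k1·P(g1)T(g2|g1) + k2·P(g1)[g1=g2]`, loci
independent (linkage equilibrium is assumed, as in the source system).
`ml_relationship()` maximises over the classes and reports
`r = k1/2 + k2`. Continuous-r estimators and sibship reconstruction are out
of scope; the four classes are the classification set of the standard ML
relatedness tools.

Parentage: `parentage_lod()` is the log-ratio of "candidate is a parent"
against "candidate unrelated", with the trio transition when a parent is
already known. Genotyping error is folded in through an observed-given-true
genotype mixing matrix derived from the per-allele substitution model — the
same model the simulator uses — rather than the class-based error model of
the reference software; the two agree to first order in the error rate.
Mendelian exclusions at zero error contribute a guarded `log(1e-300)`
(≈ −691) per locus instead of `−Inf`, keeping multilocus scores finite and
sortable. All per-locus matrices are precomputed once per frequency set, so
batch scoring is a table lookup.

`assignment_confidence()` reproduces the simulation stage of
likelihood-based assignment: simulated offspring, candidate sets in which
the true parent is present with probability `prop_candidates_sampled`, loci
typed with probability `prop_loci_typed` (0.99), error applied throughout;
the statistic is Delta, the LOD gap between best and second-best candidate,
and thresholds are the smallest Delta at which the success rate among
qualifying assignments reaches 95% (strict) and 80% (relaxed). The source
description's "0.7% sampled parents" is treated as a misprint for a
proportion of 0.7 — at 0.007 virtually no true parent would ever be in the
candidate set and assignment rates could not reach the levels reported —
and the literal value remains available through the argument. The stated
0.06% inbreeding rate is ignored in the likelihoods (its effect is far
below the error-model term at that magnitude); this is a documented
deviation. Default `n_sim` is 10,000 (the reference workflow uses 100,000;
the threshold quantiles stabilise well before that, and the parameter is
exposed).

## 7. The analysis pipeline

`run_*_analysis()` functions orchestrate the named analyses on tidy data
frames and return `owl_report` objects (model-set table + averaged
estimates + analysis-specific extras). Candidate sets are hard-coded to
match the published tables line by line — occurrence (11 binomial models,
year random), productivity (5 zero-inflated Poisson models over all nests
with year random; 5 more over nests ever hosting a family unit with nest
and year random), condition (5 Gaussian models, nest and year random, both
nest sets), lifetime reproductive success (null vs strategy, zero-inflated
negative binomial), and the two CJS sets (7 family-structure models, 6
body-condition models, effort on recapture) — rather than generated by
all-subsets search, so reports are directly comparable. The occurrence
analysis excludes nest as a random term (mirroring the source's convergence
constraint); `fit_glm()`'s boundary fallback makes this mostly moot on
synthetic data, where the generator contains no nest effect. Analyses abort
with a clear error on degenerate responses (e.g. no family units at all:
complete separation).

Reports are deterministic given their input; all randomness lives in the
generators, which are deterministic given `sim_config(seed = )` (each
generator derives a distinct stream from the config seed, so pipeline
stages are mutually decorrelated but reproducible).

## 8. Problem sizes and numerical choices

The shipped tests run at sizes chosen to make every recovery check
informative while keeping the suite quick on one core: the shared synthetic
study uses the full default population (450 nests × 13 seasons ≈ 5,850
nest-years, ≈ 15,000 chicks); survival recovery uses 2,000 marked chicks
over 10 occasions (the estimate SEs are then ≈ 0.015 for juvenile classes
and ≈ 0.017 for adults, so the ±0.03 recovery checks have ≈ 2-sigma room);
the CJS likelihood is verified against exhaustive path enumeration for all
histories up to 6 occasions (tolerance 1e-10); permutation calibration uses
500 null replicates at the study's group sizes; kinship classification uses
100 simulated pairs at the full 17-locus panel. Optimiser settings: BFGS,
`reltol 1e-10`, zero starts — CJS logit surfaces are smooth and unimodal in
these designs; probability underflow is guarded at 1e-300 throughout.

## 9. Limitations — what passing tests do and do not show

The simulator emulates the *statistical* structure the analyses assume, not
the field system: no floaters, no movement trajectories or
habitat-boundary effects, no nest-level random heterogeneity (so mixed
models legitimately collapse to their fixed-effect limits on synthetic
data), dispersal-distance shapes are stand-ins, and the antipredator
experiment is not simulated at all (its Bayesian analysis is out of scope).
Parameter-recovery successes therefore demonstrate that the estimators are
correct and well calibrated under their own assumptions — they cannot
validate those assumptions against real owls, and the headline field
estimates quoted as generating values (7%/3%, survival 0.29/0.21/0.71,
attendance 1.37, condition 0.02, productivity 0.27) are inputs here, not
reproduced field results. Real-data ingestion goes through the same CSV,
MARK `.inp` and GenePop readers the tests exercise, so swapping synthetic
for field tables is mechanical.
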