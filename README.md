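# eventseg

Statistical machinery for naturalistic **event segmentation** experiments:
observers watch a movie and press a button whenever one meaningful event
ends and another begins, while EEG is recorded. The package implements the
full analysis chain from button-press streams to group-level inference —
paired with a synthetic-data generator, because the clinical recordings such
studies rest on cannot be shared.

## What it does

**Behavioural side.** The movie is cut into 2-s bins; a per-bin coding marks
which of nine situational change types (character, character–character,
character–object, temporal, large/small spatial, cause, goal, scene cut)
occur. The probability that subject *s* marks a boundary in bin *b* is
modelled as a mixed-effects logistic regression

> logit P(response) = β₀ + u_s + β_count · n_changes + β_int · group · n_changes,  u_s ~ N(0, σ²)

fit by maximum likelihood (`lme4`), with odds ratios `exp(β)` and Wald 95 %
intervals. Group demographic tables are audited with pooled-variance t tests
recomputed from printed means/SDs and a Pearson χ² on reconstructed counts.

**Neurophysiological side.**

* `build_interval_pairs()` — boundary (BI) vs no-boundary (NBI) 2-s
  segments: 4-s response pruning, per-clip count-matched NBI sampling,
  virtual markers copying the BI marker offset, realignment to
  [marker − 1 s, marker + 1 s].
* `compute_band_csd()`, `compute_dics_filters()`, `project_source_power()` —
  a DICS-style frequency-domain beamformer: Hann-tapered band CSD at 0.5-Hz
  resolution, unit-gain filters `W = (LᵀC_r⁻¹L)⁻¹LᵀC_r⁻¹` with 5 %
  regularization and a rank-3 free-orientation leadfield, common across
  conditions; per-voxel power as the dominant eigenvalue of `W Re(C) Wᵀ`.
* `cbpt()` — cluster-based permutation test: paired t map, two-sided
  cluster-forming threshold, connected components per sign, `t_sum` cluster
  statistic, max-statistic sign-flip null (compiled permutation core),
  Monte-Carlo p with the +1/+1 convention.
* `loo_cbpt_metrics()` / `compare_group_metrics()` — leave-one-out jackknife
  distributions of cluster **size** (significant voxels) and **relT_sum**
  (t_sum per voxel), compared across groups by Wilcoxon–Mann–Whitney with
  effect size r = |z|/√N.
* `localize_modulation()` — DBSCAN (from scratch; eps = 0.75 cm =
  1.5 × grid size, minPts = 5) on the top 1 % of condition differences with
  cerebellum exclusion and atlas labelling.

Every stage takes and returns tibbles where the data are tabular, has
`tidy()`/`glance()`/`autoplot()` methods for its result objects, and is
exercised against independent oracles (exhaustive enumeration, brute-force
flood fill / density closure, closed-form moments, scikit-learn's DBSCAN).

## Worked example

```r
library(eventseg)

# 1. simulate a study: coding table, two groups of responders
cfg  <- sim_config(seed = 42, n_subjects_per_group = 30)   # 900 bins x 2 s
tab  <- simulate_change_table(cfg)
resp <- simulate_responses(tab, cfg)

# 2. behavioural model
fit <- fit_mixed_logit(build_designs(tab, resp)$count)
tidy(fit)
#> # A tibble: 4 × 8
#>   term            estimate std_error conf_low conf_high odds_ratio or_low or_high
#>   <chr>              <dbl>     <dbl>    <dbl>     <dbl>      <dbl>  <dbl>   <dbl>
#> 1 (Intercept)      -3.20      0.0960   -3.38    -3.01       0.0409 0.0339  0.0494
#> 2 n_changes         0.265     0.0271    0.212    0.318      1.30   1.24    1.37
#> 3 group            -0.0269    0.136    -0.293    0.239      0.973  0.746   1.27
#> 4 n_changes:group  -0.0518    0.0391   -0.128    0.0248     0.950  0.879   1.03

# each additional situational change multiplies the odds of a boundary
# response by ~1.30 (95% CI 1.24-1.37) in group 0, slightly less in group 1;
# the generating values (log-odds 0.30, interaction -0.09) sit inside both
# Wald intervals at this seed

# 3. source statistics on simulated voxel power (15 subjects, 1000 voxels)
spec <- source_sim_spec()                      # 1-SD shift in 20 voxels
sim  <- simulate_power_dataset(spec, n_per_group = 15, seed = 42)
adj  <- build_adjacency(sim$grid)
res  <- cbpt(sim$groups$group1$bi, sim$groups$group1$nbi, adj,
             n_perm = 1000, seed = 42)
glance(res)
#> # A tibble: 1 × 8
#>   n_clusters n_significant    min_p max_abs_t_sum n_perm alpha alpha_form    df
#>        <int>         <int>    <dbl>         <dbl>  <int> <dbl>      <dbl> <int>
#> 1         42             1 0.000999          36.8   1000  0.05       0.05    14

# one significant cluster at the permutation floor p = 1/1001; 7 of its
# voxels lie inside the planted 20-voxel region (the remainder of the
# planted voxels fall below the cluster-forming threshold at this seed)
```

See `vignettes/event-segmentation-pipeline.Rmd` for the models, parameter
conventions and the reasoning behind every under-determined design choice.

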