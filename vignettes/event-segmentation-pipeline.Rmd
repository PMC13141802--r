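---
title: "Event segmentation analysis: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event segmentation analysis: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventseg)
library(dplyr)
```

## The scientific problem

In a naturalistic event segmentation experiment, observers watch a silent
movie and press a button whenever they feel one meaningful event has ended
and another has begun. Two families of questions follow:

1. **Behavioural**: how does the probability of marking an event boundary in
   a short time bin depend on the objective situational changes occurring in
   that bin (changes of character, location, goal, scene cut, and so on),
   and does that dependency differ between groups (e.g. neurotypical
   adolescents versus adolescents with autism spectrum disorder)?
2. **Neurophysiological**: how does band-limited oscillatory source power
   (theta 4–7 Hz, alpha 8–12 Hz, beta 15–30 Hz) differ between 2-s EEG
   segments containing a boundary response (*boundary intervals*, BI) and
   count-matched segments without one (*no-boundary intervals*, NBI), and do
   those modulations differ between groups in extent and strength?

The clinical EEG recordings behind such studies are not shareable, so this
package pairs every analysis stage with a synthetic-data generator that
reproduces the statistical structure the stage assumes. All claims the test
suite makes are claims about this generative model, not about any particular
recording; the point of the package is that the *machinery* — interval
construction, beamforming, cluster permutation statistics, jackknife group
comparison, density-based localization, mixed models — is correct, fast and
reproducible.

## Interval construction

`prune_responses()` enforces a minimum 4-s gap between button presses with a
greedy left-to-right scan (a press is kept iff it is at least 4 s after the
last kept press). Whether such a rule should be greedy or re-evaluated after
deletions is ambiguous in general; we implement the greedy scan because it
is the only single-pass rule and makes the no-overlap guarantee provable:
with 2-s windows and a 4-s minimum gap, realigned boundary windows can never
overlap.

`classify_bins()` cuts the movie into half-open bins `[t, t + 2)`; a
response exactly on an edge belongs to the later bin. `build_interval_pairs()`
then, per movie clip: samples as many NBI bins as there are BI bins (without
replacement, with a dedicated seeded generator so that behavioural and EEG
stages reproduce independently), sorts both lists by time, pairs them in
order, copies each BI's within-bin marker offset onto its paired NBI as a
*virtual marker*, and realigns every segment to `[marker − 1, marker + 1]`.

Two situations are under-determined and resolved conservatively:

* A BI whose realigned window would cross a clip edge is dropped with a
  warning (edge windows would mix data across the break between clips).
* An NBI candidate bin must contain no response anywhere in
  `(bin start − 1, bin end + 1)`. The natural rule — "the realigned window
  around the virtual marker holds no response" — cannot be checked before
  the marker is known, and the marker is only known after pairing; the
  widened-window rule guarantees it for *every* possible marker offset.

## The beamformer

The frequency-domain (DICS-style) beamformer estimates source power on a
regular grid from a sensor cross-spectral density (CSD). `compute_band_csd()`
Hann-tapers each 2-s segment, takes discrete Fourier coefficients at the
0.5-Hz-spaced bins inside the band, and averages the rank-1 outer products
over segments and bins. The "0.5 Hz smoothing" is realized as this averaging
over the segment's natural 0.5-Hz frequency resolution; no multitaper is
used, because averaging adjacent natural bins is the simplest construction
consistent with that bandwidth.

`compute_dics_filters()` builds, per voxel with a sensors × 3
free-orientation leadfield \(L\) (the rank-3 source model conventional for
EEG), the unit-gain minimum-variance filter

\[
W = (L^\top C_r^{-1} L)^{-1} L^\top C_r^{-1},
\qquad
C_r = \mathrm{Re}(C) + \lambda\,\frac{\mathrm{tr}\,\mathrm{Re}(C)}{n_{\text{sens}}} I ,
\]

with \(\lambda = 0.05\) (5 % of mean sensor power) by default. The filter is
computed once from the CSD of the *appended* BI + NBI segments and applied
unchanged to each condition's CSD — the common-filter contract that makes
condition contrasts interpretable. Unit gain \(W L = I_3\) holds to 1e−8 on
well-conditioned inputs and is asserted in the tests.

`project_source_power()` reports, per voxel, the largest eigenvalue of the
3 × 3 source cross-spectrum \(W\,\mathrm{Re}(C)\,W^\top\) (the
dominant-orientation convention); the trace is available via
`summary = "trace"`. The eigenvalue is the default because it is invariant
to the arbitrary orientation basis of the leadfield columns and matches the
"strongest dipole orientation" reading of absolute power; with a single
dominant source the two conventions rank voxels nearly identically. Only the
real part of the CSD enters filters and power; imaginary parts are retained
on the `csd_matrix` for inspection.

The synthetic leadfields (`simulate_leadfield()`) use random orthonormal
column triplets per voxel. This deliberately abstracts away volume
conduction: all voxels are equally visible, so localization failures in
tests indicate algorithmic defects, not forward-model idiosyncrasies. The
price is that spatially correlated leadfields of neighbouring real voxels —
and hence beamformer leakage blur — are not emulated.

## Cluster-based permutation testing

`cbpt()` implements the nonparametric cluster test for a paired BI/NBI
contrast: a dependent-samples t map over voxels, thresholded at the
two-sided t critical value at `alpha_form = 0.05`; connected components of
suprathreshold voxels (6-connectivity on the lattice by default), separately
per sign; cluster statistic `t_sum`; and a max-statistic null obtained by
independently flipping each subject's condition labels (the `2^n` sign-flip
scheme, sampled `n_perm` times or exhausted for small n). The Monte-Carlo p
value uses the `+1/+1` convention, so it cannot fall below
`1 / (n_perm + 1)`.

Choices worth stating:

* **Cluster-forming threshold.** A two-sided paired-t quantile at α = 0.05
  is the common default of the major EEG statistics toolboxes and is
  configurable via `alpha_form`. The permutation test is valid for any
  choice; the threshold trades sensitivity to focal versus broad effects.
* **Two-sided family-wise control.** The null records the maximum of
  |t_sum| over *both* signs, and positive/negative clusters are reported
  separately — matching how condition contrasts of either direction are
  usually reported.
* **Space-only clustering.** The pipeline contrasts band-averaged power, so
  the time and frequency dimensions collapse before clustering; only spatial
  adjacency matters here.
* **Performance.** The permutation loop (t maps, thresholding, union-find
  clustering, max statistic) is compiled (Rcpp); sign flips only change
  per-voxel means, not sums of squares, so each permutation's t map costs a
  single matrix product.

The suite validates the test's operating characteristics under the study
conditions (15 paired subjects, 10 × 10 × 10 grid at 0.5 cm, 200
permutations): family-wise type-I error within [0.03, 0.08] over 500 null
simulations; ≥ 90 % detection and mean Jaccard overlap ≥ 0.5 for a planted
1-SD, 20-voxel connected effect over 50 replicates; and agreement of the
sampled null with the exhaustive 32-pattern null at n = 5 (Kolmogorov
distance < 0.05 at 2 000 draws).

## Leave-one-out group comparison

Because cluster statistics of independently thresholded group analyses
cannot be compared directly, the group contrast uses a jackknife:
`loo_cbpt_metrics()` reruns the full CBPT once per omitted group member and
records, per iteration, the total number of significant voxels (*size*) and
the summed t values over those voxels divided by the size (*relative
modulation strength*, `rel_t_sum`; signed, so down-modulations are
negative). `compare_group_metrics()` then applies a Wilcoxon–Mann–Whitney
test per metric with effect size `r = |z| / sqrt(n1 + n2)`.

Resolved ambiguities:

* Iterations without a significant cluster contribute `(0, 0)` rather than
  being dropped — dropping them would condition the comparison on
  significance and bias both metrics upward. Groups in which *no* iteration
  yields a cluster should simply not be compared.
* When several clusters are significant in one iteration, `size` sums their
  voxels and `rel_t_sum` is computed over the union of the dominant sign's
  clusters; multiplicity must be handled even if it is rare.
* Jackknife samples are strongly dependent (each pair of iterations shares
  n − 2 subjects), so the rank-sum p values are descriptive of the
  resampling distribution rather than exact; the test is applied regardless
  because that is the established convention for this comparison, and the
  caveat is stated here and in the function documentation.
* `wilcoxon_mann_whitney()` uses midranks, a tie-corrected normal
  approximation without continuity correction, and exhaustive enumeration
  for `n1 + n2 ≤ 12` without ties.

## DBSCAN localization

`select_top_voxels()` takes the top 1 % (configurable) of BI − NBI
differences in the direction of the effect, after excluding cerebellar
voxels, with ties at the cutoff broken by voxel id. `dbscan_cluster()`
clusters the selected voxels with eps = 0.75 cm (1.5 × the 0.5-cm grid
spacing — reaching face and edge neighbours, distance 0.5 and ≈ 0.707 cm,
but not cube-diagonal neighbours at ≈ 0.866 cm) and minPts = 5, counting
the point itself in its neighbourhood (the classic convention).

Core-point membership and the partition of core points are order-invariant
consequences of density reachability. Border-point assignment is the one
order-dependent part of DBSCAN; we grow clusters to completion from
unvisited core points in ascending point-id order, with each cluster
claiming every point it can reach before the next cluster starts — the
expansion semantics of the original algorithm and of the scikit-learn
implementation, so partitions agree exactly with that reference (verified
on 100 random point sets), while remaining fully deterministic.

`label_clusters()` tallies atlas region labels per cluster;
`make_toy_atlas()` ships a deliberately artificial block parcellation with a
synthetic "cerebellum" corner so the exclusion path is exercised. No real
anatomical atlas is included.

## Behavioural models

`fit_mixed_logit()` fits, by maximum likelihood (Laplace approximation,
`lme4::glmer`), logistic models of per-bin boundary responses with a
subject-level Gaussian random intercept: the *count model*
`response ~ n_changes * group + (1 | subject)` and the *type model* with the
nine change-type indicators each interacting with group. Wald 95 % intervals
are reported as the frequentist analogue of credible intervals and odds
ratios are exact exponentials of the estimates. This is an analogue of a
Bayesian MCMC fit of the same likelihood — point estimates and interval
endpoints agree closely at these sample sizes under weak priors — not a
replication of posterior geometry; no sampler dependency is introduced.
Boundary (singular) variance estimates are treated as converged fits, since
they are the expected outcome when the true intercept SD is near zero.

`mean_event_length()` is movie duration divided by response count;
`event_length_test()` compares groups with a pooled two-sample t test.
`t_from_summary()` and `chisq_from_table()` recompute printed group
comparisons from summary statistics (pooled-variance t; Pearson chi-square
without continuity correction), which is how demographics tables are
audited when raw data are unavailable.

## The synthetic-data generator

The generator's defaults encode the study conditions: 30 subjects per group;
a 30-min movie in three 10-min clips, cut into 900 bins of 2 s (60 frames at
30 fps); response model intercept −3.26, count slope 0.30, group × count
interaction −0.09 (the fitted behavioural coefficients), random intercept
SD 0.5; sensor segments of 2 s at 300 Hz (600 samples). Situational-change
probabilities per type are a modelling default chosen so that per-bin counts
rarely exceed 5 (matching the empirically observed 0–5 range without
truncating the generative model, which would bias it); no claim is made that
they match any particular film. Change flags are independent across types
and bins — real codings are temporally structured, which matters for
autocorrelation of responses but not for the regression stage these data
feed.

Voxel power data are Gaussian on the log scale: baseline plus
`effect_delta × 1[planted voxel, BI condition]` plus i.i.d. noise; the
planted region is a compact lattice ball of 20 voxels grown from the grid
centre (connected under 6-connectivity), and group 2's extent *and* shift
are scaled by `group_scale`. What the generator does **not** emulate —
spatially correlated noise, inter-subject alignment error, beamformer
leakage, autocorrelated behaviour — bounds what passing tests show about
real recordings: they certify the statistics under the stated model, and
the type-I-error simulation in particular relies on exchangeability that
real data satisfy by construction of the sign-flip scheme, not on
Gaussianity.

## Problem sizes and numerical choices

Simulation-based checks run at the sizes stated above (500 null datasets;
50 recovery replicates; 20 jackknife replicates of 2 × 15 leave-one-out
CBPTs; 20 mixed-model replicates at 60 × 900 observations), chosen so the
whole suite completes in minutes on a single core while keeping Monte-Carlo
error well inside the asserted margins. Degenerate inputs are defined
rather than left to chance: zero-variance voxels contribute t = 0; a
rank-sum comparison of two identical constant samples returns z = 0, p = 1;
an empty suprathreshold set is a valid (empty) cluster result; mean event
length without responses is an error, not NaN. Seeds flow top-down: every
public stochastic function takes a seed, and multi-stage runs derive
independent sub-seeds so stages can be reproduced in isolation.

## Known limitations

* The beamformer is a toy in the forward-model sense: abstract lattices and
  random orthonormal leadfields, no volume conduction, no coregistration.
* Jackknife rank-sum p values inherit the dependency caveat above.
* The frequentist mixed-model fit approximates the Bayesian original; with
  strongly informative priors or tiny samples the two would diverge.
* The DBSCAN reference agreement is up to label permutation; border points
  tied between clusters follow expansion order, which is deterministic but
  one of several defensible conventions.
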