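---
title: "How sample size shapes the stability of brain-behavior correlation maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How sample size shapes the stability of brain-behavior correlation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Task-fMRI studies routinely correlate per-participant activation (a contrast
image, one 3D volume per person) with a behavioral score across
participants, voxel by voxel. With the sample sizes common in cognitive
neuroscience (20-30 participants), two pathologies are expected on
first principles: the map of "significant" voxels changes substantially from
sample to sample (both false negatives and false positives), and the
correlation magnitudes in whichever voxels or latent variables survive are
inflated — the winner's curse. `brainstab` packages the machinery needed to
study both effects quantitatively: a synthetic cohort generator with a known
embedded effect, a disjoint subsampling design, two analysis arms
(univariate voxelwise correlation maps and single-measure behavioral partial
least squares), and map-similarity metrics.

Everything runs at desk scale with no imaging data downloads; real cohorts
(one NIfTI contrast volume per participant, a binary mask, a covariate
table) can be ingested through the same interfaces.

## The synthetic cohort model

### Covariates

Each participant gets an age (years), a mean frame displacement (FD, mm; a
per-participant head-motion summary) and a behavioral score (proportion
correct). A trivariate Gaussian latent with a target correlation matrix is
built by Cholesky factorization and scaled to the marginals. Two presets are
provided:

* `dallas_covariates()` — an aging working-memory cohort: age-FD r = 0.46,
  age-behavior r = -0.48, FD-behavior r = -0.29; ages span 20-94 years;
  behavior 0.75 ± 0.10; FD 0.30 ± 0.12 mm (head motion increases with age,
  and FD in older samples commonly sits around 0.2-0.4 mm).
* `hcp_covariates()` — a young-adult cohort: age-FD r = 0.12, age-behavior
  r = -0.09, FD-behavior r = -0.19; age 28.72 ± 3.74; behavior 0.80 ± 0.10;
  FD 0.15 ± 0.05 mm.

The aging preset does **not** use a plain Gaussian age marginal. Aging
cohorts are typically recruited to be balanced across age brackets, and a
stratified subsampling design that needs, say, 7 disjoint subsamples of 24
with 6 participants per age group requires at least 42 members in *every*
bracket of a 171-person cohort — which a Gaussian with SD 19 years fails
with high probability. Age is therefore generated as an equal-weight mixture
of uniforms over the four brackets 20-35, 36-55, 56-69 and 70-94 years,
realized by mapping the rank of the Gaussian age latent through the mixture
quantile function. This yields balanced strata by construction (43/43/42/43
at n = 171) while preserving the rank coupling with the other covariates.
Because a monotone non-affine transform slightly attenuates Pearson
correlations, the latent correlation is inflated by a numerically computed
attenuation factor (about 0.977, obtained by quadrature), so the *achieved*
Pearson correlations match the targets. The young-adult preset keeps the
plain affine-Gaussian age.

Behavior is clipped to [0, 1] after scaling. At the default marginals fewer
than 1% of draws hit the bounds, and the induced distortion of embedded
correlations is below 0.02 (measured in the test suite, not assumed).

### Voxel data

A ground-truth pattern (`make_truth()`) assigns each voxel a target
population correlation `rho_v` with behavior:

* `localized_strong` — a compact sphere (default radius 3 voxels) at
  rho = 0.5;
* `diffuse_weak` — 30% of voxels at rho = 0.15;
* `null` — all zeros.

These presets bracket the two regimes discussed in the simulation
literature: strong-localized effects stabilize at modest n, weak-diffuse
ones may not even at n = 150. Voxel values are generated as

    X[i, v] = rho_v * z_i + sqrt(1 - rho_v^2) * eps[i, v]

with `z` the standardized behavior latent and `eps` independent standard
normal noise, so the population correlation of voxel `v` with the latent is
exactly `rho_v`. The correlation is embedded against the pre-clipping
latent; the small clipping distortion is measured by simulation. An optional
per-voxel age loading adds covariate signal to the brain so that
residualization has something to remove (off by default: the default truth
is a pure brain-behavior correlation).

The default grid is 20 x 20 x 20 voxels at 3 mm isotropic (~8,000 voxels):
large enough for spatial overlap statistics, small enough that full
resampling experiments run in seconds to minutes on one core.

What the generator deliberately does **not** emulate: spatial
autocorrelation (contrast images in practice are smoothed, so neighboring
voxels are strongly correlated), scanner or site effects, and
non-Gaussian noise. Consequences: suprathreshold sets here are
"salt-and-pepper" rather than blobs, cluster-extent behavior is not
represented, and the in-sample PLS brain-score-behavior correlation is more
strongly inflated than in real data (with thousands of independent voxels
and small n, the sample-optimal latent variable nearly interpolates the
behavior). Passing tests therefore certify the *machinery* and the
*qualitative* sample-size behavior — decreasing correlation inflation and
increasing map similarity with n — not real-data effect magnitudes.

## Subsampling design

`default_schedule("dallas")` is 12 x10, 24 x7, 36 x4, 48 x3, 60 x2, 72 x2,
84 x2 (size x number of subsamples); `default_schedule("hcp")` is 20, 40,
60, 80 (x10 each), 100 x8, 120 x7, 140 x6, 160 x5, 210 x4, 280 x3, 420 x2.
All subsamples of one size are pairwise disjoint (sampling without
replacement across subsamples); participants may recur across different
sizes, which use fresh draws. Stratified draws take exactly
`size / n_strata` members per age bracket, so the age composition is
identical across all subsamples of a size; sizes not divisible by the
stratum count are rejected with a clear error rather than silently
unbalanced. Within a stratum, selection is uniform at random.

Reproducibility: every stochastic stage (cohort noise, each subsample draw,
each permutation and bootstrap stream) takes a seed derived from the master
seed through a fixed integer mix (`derive_seed()`), so adding a size or a
stage never perturbs the draws of another, and an entire experiment is a
pure function of (configuration, seed).

## The univariate arm

Age and FD are regressed out of behavior and out of every voxel
(OLS with intercept) and the analysis proceeds on residuals; by default the
regression is computed *within each subsample*, matching a per-analysis
nuisance correction (a cohort-level variant is a config switch). The
voxelwise Pearson correlation of residuals is then the partial correlation
given the covariates, and is mapped to t via

    t_v = r_v * sqrt(df / (1 - r_v^2)),  df = n - 2 - q

with q = 2 nuisance covariates, matching a second-level regression with
behavior, age, FD and an intercept. A one-sample t map over contrast values
(`group_ttest()`, df = n - 1) serves as the task-effect surrogate.

Numerical choices: |r| = 1 maps to a documented sentinel of ±1e6 rather
than ±Inf; zero-variance voxels get r = 0 plus a flag (so similarity
metrics never propagate NaN) and flagged voxels are excluded from
thresholded sets; the threshold comparison is inclusive (`>=`).

## The behavioral PLS arm

With a single behavioral measure and one image per participant, the
brain-behavior correlation structure is the 1 x V vector `r` of voxelwise
correlations, and its singular value decomposition is closed-form: singular
value `s = ||r||_2`, salience (voxel weights of the latent variable)
`u = r / ||r||_2`. Brain scores are the projection of the
column-standardized brain matrix onto the salience; their correlation with
behavior summarizes how well the whole-brain pattern tracks behavior. The
closed form is verified against a general-purpose SVD in the tests.

Inference:

* **Permutation p for the LV** — behavior is permuted uniformly (equivalent
  to permuting rows of X), the singular value recomputed each time, and
  `p = (1 + #{s_perm >= s_obs}) / (1 + n_perm)`. The add-one form keeps p
  strictly positive; a raw proportion can return 0, which breaks log-scale
  reporting. Default `n_perm = 1000`.
* **Bootstrap ratio (BSR)** — participants are resampled with replacement
  jointly (rows of X with y); each replicate's correlation vector is
  sign-aligned to the observed one by inner product (the single-LV case of
  procrustes alignment), and `bsr_v = r_obs_v / SD_boot(r*_v)`. Default
  `n_boot = 1000`. The ratio is computed on the *unnormalized* correlation
  vector rather than the unit-norm salience: per-replicate normalization
  would couple every voxel to the singular value; on the unnormalized scale
  the ratio matches "salience / SE of salience" up to a common constant.
  Voxels with zero bootstrap SD get bsr = 0 and a flag; replicates with
  constant behavior are redrawn (at most 10 retries, then an error).
* Residualization is applied once, upstream, to both X and y; the
  permutation does not recompute it (a Freedman-Lane-style recomputation is
  a known alternative, not implemented).

Column standardization of X before the brain-score projection is a fixed,
documented convention; for a fixed sample it does not change the
correlation of brain scores with behavior, but it makes score scales
comparable across subsamples.

## Stability metrics

For each pair of maps within a sample size:

* **Spearman rho** over all masked voxels of the *unthresholded* maps
  (average ranks on ties, then Pearson on ranks); constant maps are an
  error rather than a silent NaN.
* **Jaccard index** |A∩B| / |A∪B| of the *thresholded* voxel sets, by
  default positive tail at threshold 3 — the conventional uncorrected
  cutoff for both t and BSR maps (voxel-level p ≈ .003). The 0/0 case
  (both sets empty) is defined as 0 with a warning attribute: "nothing
  replicated" counts as zero stability. A negative-tail variant and the
  Dice coefficient are provided but off the main path.
* **Penetration maps** count, per voxel, how many thresholded maps of a
  size contain it; counts below 2 are zeroed in the reported volume, and no
  clustering is applied. With a known truth, the voxels reaching maximal
  penetration at the largest size should sit inside the true support —
  the pipeline's end-to-end recovery check.

`overlap_summary()` aggregates to per-(size, method) means, and
`compare_methods()` pairs the per-size mean Jaccard of the two arms and
reports a paired t statistic over sizes (df = number of sizes - 1).

## Problem sizes used in the tests

The test and acceptance suites run the full pipeline on cohorts of 80-400
participants over grids of 6^3 to 12^3 voxels with 100-200 permutations and
bootstraps; generator-recovery checks use n up to 100,000 for covariates
(where the Monte-Carlo error of a correlation is ~0.003) and n = 10,000 for
voxel embedding. These sizes were chosen so that every property is measured
with known Monte-Carlo error while a complete run stays in the minutes
range on a single core; the defaults users see (`n_perm = n_boot = 1000`,
20^3 grid) remain the conventional analysis scale.

## Known limitations

* Independent voxel noise (no spatial autocorrelation model) — see above.
* Single behavioral measure only; multi-condition, multi-group and
  multi-LV (rotated) PLS are out of scope, as is the block-level
  task-contrast PLS variant — the task-effect surrogate here is the
  one-sample t map.
* No FWE / random-field / cluster-extent correction; the similarity surface
  works on uncorrected threshold-3 maps throughout.
* No resampling between grids; all volumes of a cohort must share one grid.
* The gray-matter mask of a real study is whatever the user supplies; for
  synthetic cohorts the full grid is the mask, and voxels that are NaN in
  any participant are removed at assembly.
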