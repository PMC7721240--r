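# brainstab

Sample-size stability of voxelwise brain-behavior correlations in task
fMRI.

## The problem

A standard design in cognitive neuroscience correlates per-participant task
activation (one contrast volume per person) with a behavioral score, voxel
by voxel, across participants. At the sample sizes most studies use (20-30
participants) these correlation maps are unstable: the set of
suprathreshold voxels changes from sample to sample, and the correlation
magnitudes that survive are inflated — the "winner's curse". `brainstab`
is for methodologists and study planners who want to measure those effects
directly: it simulates cohorts with a *known* embedded effect, re-analyses
many pairwise-disjoint subsamples of graded sizes with two analysis arms,
and quantifies how map stability and effect-size estimates change with n.

## What it computes

For a cohort with brain matrix **X** (participants × voxels), behavior
**y**, and nuisance covariates (age, mean frame displacement), both arms
first residualize **X** and **y** on the covariates, then:

* **Univariate arm** — voxelwise Pearson correlation r_v = cor(X_v, y),
  mapped to t via t_v = r_v √(df / (1 − r_v²)), df = n − 2 − q; plus a
  one-sample t map as the task-effect surrogate.
* **Behavioral PLS arm** — the SVD of the 1 × V correlation structure,
  closed-form for a single behavioral measure: singular value s = ‖r‖₂,
  salience u = r/‖r‖₂, brain scores (projection of standardized **X** onto
  u) and their correlation with behavior; LV significance by permutation,
  p = (1 + #{s_perm ≥ s_obs}) / (1 + n_perm); voxel reliability by
  bootstrap ratio BSR_v = r_v / SD_boot(r*_v). Defaults: 1,000
  permutations, 1,000 bootstraps.

Stability across the subsamples of one size is measured by Spearman rho
over unthresholded map pairs, the Jaccard index |A∩B|/|A∪B| over
positive-tail threshold-3 voxel sets, and penetration maps (per-voxel
counts of overlapping thresholded maps, reported from 2 upward).

The synthetic generator embeds X_iv = ρ_v z_i + √(1 − ρ_v²) ε_iv against
the standardized behavior latent z, with covariate presets matching an
aging working-memory cohort (age-FD r = 0.46, age-accuracy r = −0.48,
FD-accuracy r = −0.29, four balanced age brackets spanning 20-94 years) and
a young-adult cohort (r = 0.12, −0.09, −0.19). Truth patterns:
`localized_strong` (compact sphere, ρ = 0.5), `diffuse_weak` (30% of
voxels, ρ = 0.15), `null`.

## Worked example

```r
library(brainstab)

cohort <- simulate_preset_cohort(
  "hcp_like",
  make_truth("localized_strong", volume_grid(c(12, 12, 12))),
  seed = 1, n = 384)

cfg <- experiment_config(
  cohort = cohort,
  schedule = data.frame(size = c(20, 40, 80, 160), n_subsamples = c(3, 3, 3, 2)),
  n_perm = 200, n_boot = 200, seed = 1)
report <- run_experiment(cfg)
print(report)
```

```
<stability_report> cohort n=384, 4 sizes, threshold 3 (positive tail)
  size     method n_pairs  mean_rho      sd_rho mean_jaccard sd_jaccard
1   20        pls       3 0.1587576 0.025535840    0.1973458 0.05727410
2   40        pls       3 0.1848788 0.007507679    0.5145433 0.04791314
3   80        pls       3 0.1807336 0.033655873    0.8596097 0.03285707
4  160        pls       1 0.1738818          NA    0.9248120         NA
5   20 univariate       3 0.1608945 0.025421380    0.1149954 0.07194243
6   40 univariate       3 0.1866182 0.007522542    0.4720811 0.05048921
7   80 univariate       3 0.1789701 0.035645912    0.9181836 0.01144576
8  160 univariate       1 0.1741958          NA    0.9609375         NA
  mean_overlap
1     29.66667
...
```

Reading the table: at n = 20 only ~11-20% of suprathreshold voxels
replicate between two disjoint subsamples (Jaccard), while by n = 80-160
the thresholded maps are nearly identical (Jaccard > 0.85) and the mean
overlap approaches the 123 voxels of the true support. The PLS arm
replicates better than the univariate arm at small n. The per-subsample PLS
records show the winner's curse:

```r
aggregate(cbind(r_brainscore_behavior, perm_p) ~ size, report$pls_table, mean)
```

```
  size r_brainscore_behavior      perm_p
1   20             0.9974829 0.004975124
2   40             0.9939898 0.004975124
3   80             0.9910870 0.004975124
4  160             0.9902632 0.004975124
```

The in-sample brain-score-behavior correlation shrinks monotonically with
n (with independent-voxel synthetic data the absolute level is inflated
toward 1 by in-sample overfitting — see the methods vignette for why, and
for what the simulation does and does not emulate). Finally,

```r
cm <- compare_methods(report)
# paired t(3) = 0.23, mean Jaccard advantage (PLS - univariate) = 0.008
```

pairs the per-size mean Jaccard of the two arms.

A thin CLI over the same functions is installed at
`inst/scripts/nbstab.R` (subcommands `simulate`, `run`, `report`; YAML
configs mirroring `experiment_config()`).

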