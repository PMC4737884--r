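---
title: "Methods: whole-brain activity mapping in the learned-helplessness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-brain activity mapping in the learned-helplessness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lhmap)
```

## The scientific problem

In the learned-helplessness (LH) paradigm, rodents exposed to inescapable
foot shocks later split into two phenotypes when shocks become escapable:
*helpless* animals that largely fail to escape, and *resilient* animals that
escape normally. Whole-brain activity read-outs — counts of c-Fos-expressing
cells per anatomical region from serial two-photon tomography in mice, or
regional 18FDG-PET signal in rats — can then be compared between phenotypes.
`lhmap` implements the downstream analysis of such an experiment:

1. **behavior**: score shuttle-box trials, summarize sessions, classify
   animals (k-means, linear discriminant classification functions, rat
   lever-press thresholds), and select extreme helpless/resilient pairs;
2. **regionstats**: a paired negative-binomial screen for differentially
   activated regions with global BH-FDR;
3. **voxelmap**: overlapping-sphere voxelization of detected cell centroids
   and a voxelwise version of the screen;
4. **stereotypy**: a bootstrap test for the group difference in mean
   within-group pairwise correlation of brain-wide activity vectors;
5. **synthio**: synthetic-data generators carrying the statistical
   structure the analyses assume.

Image acquisition, cell detection and registration are upstream of this
package: inputs are per-trial behavior tables, per-animal-by-region count
matrices, centroid tables in micrometres, and an integer label atlas.

## Trial scoring and behavioral classification

A testing trial presents a 5 s cue light followed by a 10 s escapable shock.
Shuttling within 5 s of cue onset is an **avoidance**; within 5–15 s an
**escape**, whose *escape latency* is the shuttle time minus the 5 s cue;
no shuttle within 15 s is a **failure**. Sessions comprise 35 trials of
which the first five are unscored warm-up. Session indices are the failure
count and the mean escape latency over escape and failure trials, failures
contributing the censored value 10 s.

Two conventions are genuinely open and therefore configurable:

* **Failure latency.** The censored value 10 s (the shock end) is the
  standard convention and keeps latencies in [0, 10] s; it is the default.
* **Avoidance trials** experience no shock, so no escape latency exists;
  they are excluded from the latency mean by default
  (`avoidance_as_zero = TRUE` counts them as 0 s instead).

Phenotypes are defined by k-means with k = 2 on the (latency, failures)
plane, run in raw units — seconds and counts, the axes on which the
phenotype separation is defined — with 50 random restarts under a fixed
seed; restarts remove the initialization dependence, and the cluster with
the larger mean failure count is named *helpless*. A Fisher linear
discriminant fitted to the cluster labels yields classification-function
coefficients for new animals; the package also ships the published
functions

```
R  = -4.63 + 5.67 * latency - 1.65 * failures
LH = -23.24 + 3.67 * latency + 0.53 * failures
```

with *resilient* declared iff `R > LH`. Each score is, up to a common
constant, the negative half squared Mahalanobis distance to that class
centroid plus the log class prior, so the comparison is a Mahalanobis
nearest-centroid rule.

For rats, lever presses within 20 s of shock onset over 15 trials classify
animals directly: at least 10 presses is resilient, at most 5 helpless, and
the 6–9 band is excluded.

## The paired negative-binomial screen

Imaged animals are chosen as pairs — one helpless, one resilient animal
processed in parallel — so day/batch nuisance variation (e.g. the time the
activity marker was sampled) is shared within a pair. For each region, the
counts `Y` are modelled as negative binomial with log link and conditional
mean a linear combination of the blocking factor `B` (one level per pair)
and the group indicator `G`. The group term is tested *sequentially*: a
likelihood-ratio statistic on 1 df between `~ B + G` and `~ B`, both with
the same dispersion. Pair-constant effects — including any multiplicative
offset shared by the two animals of a pair — lie in the column space of
`B` and provably do not move the statistic.

### Dispersion estimation and the reference distribution

The design is extreme for dispersion estimation: 22 observations carry up
to 13 mean parameters. Unadjusted maximum likelihood roughly halves the
dispersion here and inflates the raw type-I rate of the chi-square LRT to
about 0.2 (the same happens with any off-the-shelf unadjusted NB ML fit).
The package therefore estimates dispersion by **Cox–Reid adjusted profile
likelihood** (the profile log-likelihood penalized by half the
log-determinant of the mean-model information), which recovers the
generating dispersion essentially unbiasedly in simulation. Two reference
distributions are then used:

* **Standalone region** (`fit_paired_nb`, dispersion estimated from the
  same 22 counts): the LR statistic divided by the full-model residual
  deviance per degree of freedom is referred to F(1, n − p). This
  quasi-likelihood form absorbs the dispersion-estimation uncertainty;
  measured raw type-I is ≈ 0.02–0.04 at nominal 0.05.
* **Screen across regions** (`region_screen`, `voxel_screen`): a common
  dispersion is estimated by maximizing the summed Cox–Reid adjusted
  profile likelihood across regions (on a log-spaced grid with quadratic
  refinement, using an evenly spaced subset of at most 250 regions), then
  each region is tested by the chi-square(1) LRT with that dispersion
  treated as known. With hundreds of regions the common estimate is precise
  enough that the chi-square reference is calibrated (measured raw type-I
  0.048–0.06 under the null at 11 pairs × 500 regions).

P-values are adjusted across all regions (or voxels) by the
Benjamini–Hochberg step-up procedure (`stats::p.adjust`); the effect
direction is the sign of the `G` coefficient, `R_high` when the resilient
mean is higher.

Numerical policy: IRLS with at most 100 iterations and relative deviance
tolerance 1e-8, linear predictors clamped to ±30; non-convergence is
reported as a flagged result with `p = NA`, never dropped silently;
all-zero regions return `p = 1` with flag `all_zero`; dispersion 0 selects
the Poisson likelihood exactly, which is how the implementation is checked
against an independent sequential Poisson GLM oracle. No library-size
offset is applied by default (raw counts are the stated input); a
per-animal log-total offset is available (`offset = "total"`).

### What power is attainable here

With 11 pairs, baseline 100 and dispersion 0.2, the information bound gives
a standard error of about 0.195 for the group log-effect, i.e. a
noncentrality of ≈ 3.6 for a log-fold-change of 0.7. At a BH threshold
near p ≈ 1e-3 (20 true signals among 500 regions at q ≤ 0.05) this yields
sensitivity around 0.5 for any calibrated test — the acceptance suite
documents this operating characteristic honestly rather than inflating it
through an anti-conservative dispersion estimate. Recovered directions
match the truth essentially always, and empirical FDR stays below the
nominal level.

## Spherical-voxel density maps

The analysis voxel is a sphere of 100 μm diameter centred on a regular
grid. The spec of the sphere diameter leaves the centre spacing open; the
default spacing is one radius (50 μm) per axis so that neighbouring
spheres overlap and no tissue is missed. Membership is Euclidean distance
≤ radius with an **inclusive** boundary; a cell may contribute to several
overlapping voxels, which is intended (the map is a smoothed density, not
a partition). Candidate voxels per cell are found by index arithmetic on
the grid, and the implementation is tested for exact equality against a
brute-force all-pairs distance scan. Full 3D spheres are used; a
single-section analysis is obtained by passing a slab-shaped grid extent.
Atlas look-up uses 0-based micrometre coordinates and half-open voxel
intervals `[i*s, (i+1)*s)`, with background (label 0) and out-of-volume
points tallied separately so that tallies always conserve the cloud size.
The voxelwise screen reuses the paired NB test on per-voxel counts — the
voxel-level test statistic is an interpretation, since only FDR-adjusted
voxel maps are defined upstream — followed by BH across all voxels.

## The stereotypy bootstrap

Each animal contributes a vector of regional activity over a shared region
list (raw counts or PET intensities; no normalization by default, since
Pearson correlation is already invariant to per-animal positive affine
maps). Within-group similarity is the mean pairwise Pearson correlation
over the group's unordered pairs; the statistic is the helpless-minus-
resilient difference of these means. The null distribution resamples, with
replacement, `n1` animals and then `n2` animals from the *pooled* groups
(n1 = n2 = 11 for the mouse data, 8 for the rat data) and records the same
difference, 100,000 times. The two-sided P is twice the smaller tail
proportion of the null at the observed value, ties counted as extreme,
capped at 1 and floored at 1/`n_iter`.

Resampling with replacement duplicates animals; a duplicated pair has
correlation exactly 1. The default includes such pairs (the literal reading
of resampling individuals); `include_self_pairs = FALSE` excludes them and
redraws the rare degenerate resamples in which no valid pair remains. An
alternative "central placement" P (twice the smaller side of the empirical
CDF at the observed value) is available via `p_method = "central"`. The
implementation indexes into the pooled correlation matrix, so resamples
cost O(m²) lookups, and is verified against exhaustive enumeration of all
resamples on a pool of three animals.

One operating characteristic is worth stating plainly: this bootstrap is
**conservative**. A group resampled with replacement contains fewer
distinct animals than the true group (for n1 = 8 from a pool of 16, about
6.4 distinct on average), so the null differences spread wider than the
sampling variation of the observed statistic; in the suite's exchangeable
simulations the rejection rate at nominal 0.05 is essentially 0 under
either duplicate-handling convention. Small P-values from this test are
therefore trustworthy, but the test understates evidence — a property to
keep in mind when reading marginal P-values from it.

## What the synthetic data emulate — and what they do not

* `gen_behavior_cohort`: a two-phenotype mixture (22% helpless by default,
  the proportion typical of these cohorts), 35 trials per session, shuttle
  times from truncated normals on [0, 15) s per phenotype (resilient mean
  escape latency 1.5 s, helpless 8 s, SD 1.5 s) and per-trial failure
  probabilities (0.05 vs 0.75) — defaults chosen once as a realistic,
  clearly separated cohort. Not emulated: learning within the session,
  trial-order effects, animal-level latency heterogeneity beyond the
  phenotype means.
* `gen_region_counts`: 11 pairs, NB counts with baseline 100, dispersion
  0.2 (variance = μ + 0.2 μ²), a shared pair-level log-normal offset
  (SD 0.3) — exactly the confound the blocking factor absorbs — optional
  signal regions at a chosen log-fold-change in either direction
  ("R high" and "LH high"), an optional log-normal region profile
  (`profile_sd`) giving animals a shared anatomical pattern, and optional
  per-group animal-level noise (`stereotypy_sd`) making one group's
  profiles more similar than the other's. Not emulated: spatial
  correlation between neighbouring regions, detection artefacts, and
  region-specific dispersions.
* `gen_cell_cloud`: uniform centroids in non-overlapping axis-aligned
  boxes with Poisson counts, plus the matching integer label volume — a
  deliberately simple stand-in for registered whole-brain data that makes
  voxel/region tallies exactly checkable.

Because the generators draw independent counts per region, passing tests
demonstrate calibration and recovery under the assumed model, not
robustness to spatially structured noise in real imaging data.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds; fixed seeds give
byte-identical outputs (the determinism is itself under test). The test
suite exercises the screen at 11 pairs × 500 regions (the study's design
size), the bootstrap at 100,000 iterations, and recovery across 200
simulated screens; the acceptance script reports the same quantities at
40 simulated screens, sizes chosen so a complete run stays comfortable on
a single CPU. Known limitations: the common-dispersion screen assumes
regions share a dispersion scale; per-region dispersions are supported but
pay the power cost of the F reference; and the behavioral generator's
separation makes classification agreement near-perfect, so it exercises
correctness, not borderline-case behavior.
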