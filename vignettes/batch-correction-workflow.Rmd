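---
title: "Assessing and correcting analytical-batch effects in nontarget LC-HRMS feature tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing and correcting analytical-batch effects in nontarget LC-HRMS feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Long-term environmental monitoring by nontarget liquid chromatography
high-resolution mass spectrometry (LC-HRMS) produces feature tables —
aligned ions described by m/z and retention time, with a peak height per
sample — in which the chemical differences of interest (between sampling
months, between sewershed sites, between treatment stages) compete with
*obscuring variability*: systematic intensity differences tied to the
analytical batch in which a sample was run. When samples are acquired
over many months in several batches, batch effects can dominate any
multivariate view of the data, grouping samples by run date instead of
by chemistry.

`ntabatch` implements a complete, testable workflow for this situation:
reading MS-DIAL-style alignment exports, feature filtering, joining of
split features, normalization, empirical-Bayes batch correction,
variance decomposition (PVCA), clustering, and moderated-t differential
abundance. A synthetic-data generator with recorded ground truth stands
in for real acquisitions, so that every stage can be validated without
any download.

## Pipeline recipes

Four dataset recipes correspond to the standard ways such a campaign is
processed (`recipe_config()` / `run_recipe()`):

| recipe  | stages |
|---------|--------|
| `SB`     | filter, join, frequency filter, restrict, log2, quantile |
| `MB-unC` | same as SB (multi-batch input) |
| `MB-IS`  | filter, join, frequency filter, restrict, median-ISTD scaling, log2 |
| `MB-C`   | MB-unC stages + nonparametric ComBat |

All recipes share the filtering cascade, applied to the raw table in
this order: signal-to-noise at least 10 (inclusive; features with no
reported S/N are kept, since missingness in an export is not evidence of
noise), maximum wastewater signal strictly greater than 10 times the
mean method-blank signal (the mean includes zeros), retention time at
least 4.5 min, at least 3000 counts in at least one wastewater sample
(inclusive), then split-feature joining, then the occurrence filter
(detected — height above zero — in at least 60% of the samples of at
least one month or one site), and finally restriction to the wastewater
samples. The boundary semantics follow the literal reading of each rule;
"detection" for the occurrence filter deliberately means any nonzero
height, not the 3000-count floor, which is a separate earlier rule.

### Why MB-IS omits quantile normalization

ISTD scaling divides every height in a sample by the (geometric-mean
normalized) median height of the isotopically labelled internal
standards of that sample. This is a rank-preserving, per-sample scalar
operation. Quantile normalization replaces each column by a fixed
reference distribution looked up by rank — so applying it after ISTD
scaling reproduces, value for value, the un-scaled pipeline. A recipe
meant to show what ISTD scaling achieves must therefore not
quantile-normalize afterwards; `MB-IS` runs PVCA and clustering on the
ISTD-scaled log2 matrix. The log2 transform is kept so that the three
multi-batch variants are compared on a common measurement scale.

The divisors are rescaled to geometric mean 1 by default
(`istd_scale(normalize = TRUE)`). Dividing by raw ISTD medians (order
10^5–10^6 counts) would push all scaled heights into the regime where
`log2(y + 1)` is dominated by the `+1` offset, and the comparison across
recipes would measure that arithmetic artifact rather than the
correction. Only the between-sample ratios of the divisors carry
information; the literal division is available with `normalize = FALSE`.

## Split features

Alignment sometimes reports one analyte as two features: *duplicates*
(identical heights, a few scattered missed values) and *alternating*
features (complementary nonzero patterns). Two features are merged when
all three criteria hold: retention times within 15 s, m/z within 10 ppm
of the pair mean, and MS1 isotope-abundance ratios with a coefficient of
variation (sample sd over mean; for a pair, `|a-b| / (sqrt(2) * mean)`)
of at most 20%. Pairs are closed transitively (union-find); clusters
held together only through intermediates are flagged in the report.

The merged abundance is the element-wise **maximum** over members.
Duplicates carry identical values wherever both are present, and
alternating members carry the true magnitude in exactly one member per
sample, so the maximum reconstructs the analyte in both cases, while a
sum would double-count duplicates. Merged m/z and retention time are
total-abundance-weighted means; the surviving id (and S/N, isotope
ratio) comes from the member with the largest summed abundance, ties
resolved toward the smaller id. Features lacking an isotope ratio are
never merged, because the third criterion cannot be evaluated for them.

## Quantile normalization

The classic sorted-mean algorithm: the reference distribution is the
mean across samples of the sorted columns, and each entry receives the
reference value at its within-column rank. Tied entries — in practice
dominated by the zeros of non-detects — receive the mean of the
reference values across the tied rank span. With ties, the columns'
value multisets are therefore equal only up to tie-group averaging;
on tie-free data they are exactly identical.

## Empirical-Bayes batch correction

`combat_correct()` implements the location/scale model: after
per-feature standardization (batch-size-weighted grand mean, pooled
within-batch variance), each feature × batch has an additive estimate
`gamma_hat` (batch mean) and a multiplicative one `delta2_hat` (batch
variance). Because each is estimated from few samples, they are shrunk
toward the behaviour of all features in the batch:

* **nonparametric** (default): the prior is the empirical distribution
  of all other features' estimates; the shrunk values are weighted
  averages with weights equal to the Gaussian likelihood of the
  feature's standardized batch data under each donor's estimates. The
  integral over the empirical prior is an exact finite sum (closed via
  sufficient statistics, three rank-one matrix operations per batch),
  so this path is deterministic.
* **parametric**: normal prior on the location, inverse-gamma on the
  scale, hyperparameters by method of moments, posterior means iterated
  to a fixed point (tolerance 1e-4 on the maximum change, at most 100
  iterations — the iteration typically converges in a handful of
  steps).

The nonparametric prior is the default because batch effects of
environmental features routinely fail the parametric distributional
assumptions. No covariates enter the standardization: when sampling
month and analytical batch are inseparable by design, a covariate model
is not estimable, and the correction will also absorb any real
month-level signal that is confounded with batch — a known cost,
visible in the differential-abundance comparison before/after
correction.

Numerical guards: features with zero pooled variance are passed through
unadjusted (with a message); a feature constant within one batch (for
example, undetected there) has its within-batch scale estimate floored
at 1e-8 so likelihood weights and the final rescaling stay finite.

## PVCA

`pvca()` quantifies how much of the overall variance is attributable to
sampling month, sampling location, and analytical batch. Features are
standardized and the sample × sample correlation matrix is
eigendecomposed (`sample_pca()`); the smallest number of leading
components reaching 60% cumulative variance (`pc_n`) are each fitted
with the crossed random-intercept model

```
pc_i ~ 1 + (1 | month) + (1 | site) + (1 | batch)
```

by REML (`lme4`, with tightened optimizer tolerances so balanced
one-factor fits agree with the closed-form ANOVA estimator to 1e-6).
Per-PC variance fractions are normalized to sum to one and averaged
across the retained PCs with the renormalized eigenvalues as weights.
For single-batch data the batch term is omitted. When every level of
one factor sits wholly inside one level of another — every sampling
month inside one batch — the two variance shares are not separately
identifiable; the fit remains numerically stable (singular fits are
accepted) and the function warns.

A property worth knowing when interpreting PVCA bars: any
correlation-based sample PCA is mathematically invariant to per-sample
constant shifts or scalings, because correlation centers and scales
each column. A purely per-sample "injection efficiency" effect is
therefore invisible to this analysis — before *and* after ISTD scaling
— and quantile normalization removes any column-constant effect as
well. What PVCA attributes to batch is the *feature-specific* part of
the batch effects (compound-dependent drift, idiosyncratic shifts, and
batch-dependent detection patterns). This is why the generator's batch
model is built from feature-specific components (next section), and why
the ISTD-scaled recipe differs from the uncorrected one mainly through
the scale on which the decomposition is computed, not through the
removal of the per-sample factor itself.

## Clustering and differential abundance

Hierarchical clustering uses Euclidean distance and Ward's
variance-minimizing linkage on the same `pc_n` score dimensions used by
PVCA (the "ward.D2" convention, heights on the distance scale). Mean
silhouette widths and the gap statistic (uniform reference over each
retained dimension's range, B = 50 by default, seeded) guide the choice
of cluster count; the default `k = 7` is a configuration value, not a
rule. The gap statistic is the only stochastic stage of the pipeline.

Differential abundance fits a one-way group-means model per feature
(`limma::lmFit`) for each grouping scheme — month, site, HCA cluster —
separately; with one sample per month × site cell, interactions are not
estimable, and separate one-way fits match how contrasts are
enumerated. All pairwise contrasts (21 for 7 months, 28 for 8 sites)
are tested with empirical-Bayes moderated t-statistics
(`limma::eBayes`): prior df and prior variance estimated by moment
matching on the log residual variances, posterior variance blending the
per-feature and pooled estimates. Benjamini–Hochberg adjustment is
applied within each contrast across features (the convention of the
underlying workflow; a global variant is available via
`adjust_across = TRUE`), and significance means adjusted p < 0.05.
Effects are differences of group means on the normalized log2 scale —
after quantile normalization and batch correction they are not raw
fold changes, and they are labelled accordingly.

## The synthetic-data generator

`simulate_table()` emulates the campaign the pipeline is designed for:
56 wastewater samples (7 months × 6 trunkline sites A–E and G plus WWTP
influent and effluent), four analytical batches mapped May | June |
July–September | November+January (batch sizes 8/8/24/16), one method
blank per month, and 10 ISTD channels. Its statistical structure, all
on the log2 scale:

* baseline abundances spanning more than six orders of magnitude on the
  raw scale (background features 2^12–2^30, sporadic features
  2^8.5–2^12.5);
* batch effects `s_g c_b + gamma_gb + e_j`: a batch-wide response drift
  `c_b` (default 0, 1.2, −1.0, 1.6) with per-feature sensitivity
  `s_g ~ N(1, 0.3)`, feature-idiosyncratic shifts
  `gamma_gb ~ N(0, 0.8)`, and a per-sample efficiency
  `e_j ~ N(0, 0.25)` shared by all channels of a sample; per-batch
  variance inflation `log(delta_gb) ~ N(0, 0.25)`;
* heavy-tailed residual noise (unit-variance t with 4 df, scale 0.45):
  sporadic ion suppression/enhancement on individual peaks;
* detection-limit censoring at 500 counts plus 3% unconditional
  alignment dropout. Censoring is what makes sparsity
  response-dependent: a low-response batch or sample loses detections
  of near-threshold features, producing the batch-aligned
  presence/absence patterns seen in real data;
* planted month and site effects (10% of features each, ±1.5 log2 on
  one level), planted blank contaminants, low-RT and low-S/N features
  to exercise the filters;
* planted split pairs in both forms, with offsets inside the three
  joining criteria; rejection sampling of m/z guarantees that *no*
  unplanted pair satisfies all three criteria, so joining can be scored
  with exact precision and recall.

ISTD channels experience only `c_b + e_j` (sensitivity 1, no
idiosyncratic term, small measurement noise), which encodes the premise
of ISTD scaling: the standards capture the shared response of the run,
not compound-specific behaviour. The paper-scale magnitudes of batch
effects are not reported anywhere; all magnitudes above are free
parameters of the generator, chosen once as plausible study conditions
and frozen.

What passing tests on this generator do **not** show about real data:
the generator has no retention-time drift, no adducts or in-source
fragments, no correlated compound families (each feature is
independent), no storage-degradation trends within a batch, and its
batch effects enter exactly additively on the log2 scale. Results on
real alignments will be noisier in all of these directions.

### What the recipe ladder demonstrates

On default generator settings (2000 features), the PVCA batch fraction
is the largest experimental factor for `MB-unC`, is essentially zero
after nonparametric ComBat, and is intermediate for `MB-IS`. Given the
invariance property above, the intermediate value is *not* evidence
that a per-sample divisor removes feature-specific batch effects — it
cannot — but reflects the different scales of the recipes: quantile
normalization under batch-dependent detection rates redistributes the
zero ties and slightly amplifies batch-aligned distortions, while the
ISTD-scaled log2 matrix avoids both that amplification and the shared
drift. The acceptance suite asserts exactly this qualitative ordering,
which is the phenomenon the workflow is meant to surface.

## Measurement choices in the validation suite

* **Batch-effect recovery** (correlation between planted and estimated
  additive effects, observed ≥ 0.98 at the default settings) is
  assessed with `combat_correct()` on the log2 scale, restricted to
  features detected in every sample. Censored features realize
  detection-pattern effects rather than their planted location shifts,
  and quantile normalization partially absorbs distributional batch
  components and adds rank noise to per-feature magnitudes, so neither
  is a fair probe of the estimator itself.
* **Power/FDR of differential abundance** is simulated with Gaussian
  noise (`noise_df = Inf`), no batch effects and no per-sample
  efficiency: under heavy-tailed noise the parametric p-values are
  anti-conservative (a known limitation of moderated t on such data),
  and with censoring active the efficiency factor shifts whole samples
  across the detection limit, creating real month-level signal in the
  realized data that would be miscounted as false positives against
  the planted truth.
* **Problem sizes**: the batch-collapse check uses 2000 features; unit
  and property tests use 20–1000 features; oracle comparisons (Ward,
  silhouette) use 8 points, and the moderated-t oracle instance 5
  features. These sizes keep the whole suite in the minutes range
  while leaving every estimate far from small-sample degeneracy.

## Known limitations

* The month/batch confounding of the motivating design is fundamental:
  ComBat without covariates removes month-level signal confounded with
  batch, deflating month contrasts after correction. The
  before/after-correction overlap machinery (`contrast_overlap()`)
  exists precisely to examine what survives.
* BH control is per contrast; the union of discoveries across many
  contrasts has a higher aggregate false fraction.
* `read_alignment()` accepts a configurable column map but expects one
  header row; MS-DIAL exports with multi-row headers need to be
  trimmed first.
* The pair search for joining is windowed in m/z and exact otherwise;
  tables with hundreds of thousands of rows will want a coarser
  pre-filter before it.
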