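# ntabatch

Batch-effect assessment and correction for multi-batch **nontarget
LC-HRMS feature tables**, built for long-term environmental monitoring —
the motivating application is a municipal wastewater collection system
sampled monthly at trunkline sites and at the treatment plant's influent
and effluent, with samples analysed in four analytical batches over nine
months.

When acquisitions span months, systematic run-to-run intensity
differences ("batch effects") can dominate every multivariate view of
the data, grouping samples by run date instead of chemistry. `ntabatch`
provides the full processing chain to expose and remove them:

* **I/O** for MS-DIAL-style tab-delimited alignment exports
  (`read_alignment()` / `write_alignment()`, configurable column map,
  thousands separators accepted).
* **Feature filtering**: S/N ≥ 10, blank filter (max wastewater signal
  > 10 × mean method-blank signal), retention time ≥ 4.5 min, ≥ 3000
  counts in at least one wastewater sample, and a 60% occurrence rule
  per month or site.
* **Split-feature joining**: duplicate and alternating alignment
  artifacts merged when retention times agree within ±15 s, m/z within
  10 ppm, and MS1 isotope-abundance ratios have CV ≤ 20%; merged
  heights are the element-wise maximum over members.
* **Normalization**: `y' = log2(y + 1)`, sorted-mean quantile
  normalization, and median-ISTD scaling.
* **Batch correction**: a from-scratch empirical-Bayes location/scale
  model (ComBat), `y* = sigma_hat (z - gamma*) / sqrt(delta2*) +
  alpha_hat`, with the per-feature, per-batch estimates
  `(gamma_hat, delta2_hat)` shrunk toward the batch ensemble under a
  nonparametric (default, deterministic) or parametric prior; no
  covariates, as appropriate when sampling date and run date are
  inseparable.
* **PVCA**: eigendecomposition of the sample correlation matrix,
  crossed random-intercept REML models
  `pc_i ~ (1|month) + (1|site) + (1|batch)` on the components reaching
  60% cumulative variance, eigenvalue-weighted variance fractions.
* **Clustering**: Ward (ward.D2) HCA on the retained PCs with
  silhouette and gap-statistic diagnostics.
* **Differential abundance**: per-feature group-means models, all
  pairwise contrasts by month / site / cluster, moderated t
  (empirical-Bayes variance shrinkage), Benjamini–Hochberg FDR at 0.05.
* **A synthetic multi-batch generator** (`simulate_table()`) with
  recorded ground truth — planted batch/month/site effects, detection
  -limit censoring, blanks, ISTD channels, planted split pairs — so the
  whole pipeline is testable offline.

## Worked example

The split-feature joining criteria applied to a four-feature export
containing one duplicate pair and one alternating pair (shipped in
`inst/extdata/`):

```r
library(ntabatch)
path <- system.file("extdata", "table2_example.tsv", package = "ntabatch")
ann  <- system.file("extdata", "table2_annotation.tsv", package = "ntabatch")
aligned <- read_alignment(path, ann)
joined  <- join_features(aligned)
joined$report
#> Split-feature join: 2 clusters merged, 2 features removed ( 50.0% )
joined$table$abundance
#>     Sample_1 Sample_2 Sample_3 Sample_4 Sample_5 Sample_6 Sample_7
#> 141   165052   119320   114649    66851   149155   108584    56291
#> 185   903124   541018   723861    77930    41555   437522    69978
```

The duplicate pair (features 141/142, Δrt 7.2 s, 1.2 ppm, ratio CV
2.4%) collapses to its common heights; the alternating pair (185/187)
is reassembled by the element-wise maximum — both members report
723,861 in sample 3, and each contributes the true magnitude where the
other is blank.

A full synthetic campaign through the ComBat recipe:

```r
sim <- simulate_table(sim_config(n_features = 2000, seed = 1))
run <- run_recipe(recipe_config("MB-C"), sim$table,
                  istd_ids = sim$truth$istd_ids)
run
#> Recipe MB-C run:
#>   input             2210 features x  63 samples
#>   filter            1745 features x  63 samples
#>   join              1557 features x  63 samples
#>   ...
#> PVCA proportions:
#>    month     site    batch residual
#>   0.0444   0.1616   0.0000   0.7940
```

The filter cascade removes low-S/N, early-eluting, blank-dominated and
rare features (2210 → 1745), joining merges the planted split pairs
(→ 1557), and after correction the PVCA batch share is zero: what
remains is month/site signal and residual. The same run on the
uncorrected recipe (`"MB-unC"`) attributes ~0.44 of the variance to
batch — the contrast between those two numbers is the point of the
method.

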