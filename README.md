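# gastroclone

Somatic mutation analysis of laser-capture microdissected gastric glands.

A gastric gland is a clonal unit: one stem-cell lineage dominates it, so a
single gland sequenced at moderate depth (~23x) shows its somatic variants at
a shared VAF peak between ~0.25 and 0.5. Starting from per-variant read
counts (variant-supporting reads NV and total depth NR per microdissection),
`gastroclone` implements the statistical stages that turn such data into
biology, for anyone studying somatic evolution in normal or pre-neoplastic
epithelium:

* **Post-calling filters** — alignment-quality thresholds (ASMD >= 140,
  CLPM = 0); germline removal by a one-sided exact binomial test on counts
  aggregated over largely diploid samples (BH-adjusted, somatic at
  q < 1e-5); recurrent-artifact removal by the per-variant maximum-likelihood
  beta-binomial overdispersion rho on the grid log10(rho) = -6 ... -0.05
  (artifact when rho < 0.1 for SNVs, < 0.15 for indels).
* **Clonality and burden** — per-sample truncated binomial VAF mixture
  (minimum 4 supporting reads; K chosen by BIC), detection sensitivity
  `S = mean_i P(X >= 4 | depth_i, peak VAF)`, corrected burden `raw / S`,
  monoclonality when median VAF > 0.25.
* **Mutation-rate models** — `Burden ~ Age + (1|Donor)` mixed models (ML)
  with chronic-inflammation, metaplasia and site terms, compared by
  likelihood ratio; observed/expected burden fold changes.
* **Mutational signatures** — 96-channel SBS and 83-channel ID catalogs,
  EM exposure fitting against reference signatures, deconvolution with the
  cosine >= 0.90 acceptance rule, SBS5/40 merging, and the three-step
  per-signature fold-increase procedure for metaplastic glands.
* **Copy-number-gain timing** — fixed-mean binomial-mixture clustering of
  region SNVs into duplicated/non-duplicated,
  `T = CN_total / (CN_dup + P_ND / P_D)` with an exact Poisson-ratio
  confidence interval.
* **Panel trisomy detection** — WGS-phased heterozygous SNPs, a two-binomial
  likelihood-ratio test per panel sample (sites with > 5 reads; calls need
  BH-significance and a haplotype VAF difference >= 0.1), and an exact
  r x c Fisher test (full enumeration) for anatomical-site enrichment.
* **Driver-clone epithelium fraction** — cell fraction = VAF x local ploidy
  (capped at 1), area-weighted aggregation, and linear models for age,
  inflammation and metaplasia.

A synthetic cohort generator (`simulate_cohort()`) emulates the statistical
structure of such a study — age-proportional burdens (defaults 27.8 SNVs and
2.0 indels per year), metaplasia-accelerated burdens (2.8x / 4.4x, driven by
SBS1 x3 and SBS18 x8 signature accelerations), monoclonal VAF peaks,
germline heterozygous sites, low-overdispersion artifacts, recurrent chr20
trisomies with 2/3 vs 1/3 haplotype VAFs, and driver mutations — with full
ground truth, so every estimator is validated by parameter recovery.

## Worked example

```r
library(gastroclone)

cfg <- pipeline_config(
  sim = sim_config(n_donors = 4, glands_per_donor = 6, n_metaplastic = 4,
                   trisomy_prob = 0.3, seed = 42),
  seed = 42)
report <- run_pipeline(cfg)
print(report)
#> pipeline_report: 28 glands, 4 donors
#>   SNV rate 28.3 /yr, indel rate 2.08 /yr
#>   metaplasia folds: SNV 2.79, indel 4.36 (means)
#>   mutant epithelium fraction 0.090
```

The fitted rate model recovers the simulated 27.8 SNVs/year within its
confidence interval, from burdens corrected for the sensitivity of calling at
23x depth:

```r
print(report$rate_models$snv)
#> Mutation-rate mixed model [ age ], n = 24
#>   slope 28.26 mutations/year (95% CI 23.87-32.65)
#>   donor SD 61.59, residual SD 55.38, loglik -134.7

head(report$burdens[, c("sample", "raw_snv", "S", "corrected_snv",
                        "median_vaf", "monoclonal")], 3)
#>    sample raw_snv         S corrected_snv median_vaf monoclonal
#> 1 D01_g01    2084 0.9417869      2212.815  0.3333333       TRUE
#> 2 D01_g02    2082 0.9826848      2118.686  0.4285714       TRUE
#> 3 D01_g03    2056 0.9783668      2101.461  0.4137931       TRUE
```

`raw_snv` is the number of passing SNVs detected in the gland; dividing by
the detection sensitivity `S` gives the corrected burden; the median VAF
above 0.25 marks the gland monoclonal. Metaplastic glands show their
configured burden acceleration as observed/expected folds:

```r
report$metaplasia_folds
#>    sample fold_snv fold_indel
#> 1 D01_g07 2.780154   4.000596
#> 2 D02_g07 2.868688   4.394657
#> 3 D03_g07 2.882884   4.750311
#> 4 D04_g07 2.624976   4.305825
```

and trisomic glands get molecular timings with exact confidence intervals
(wide here, with only tens of chr20 SNVs per gland — the generated gains sit
at timing 0.2):

```r
head(report$cnv_timing[, c("sample", "n_snvs", "T", "ci_low", "ci_high")], 3)
#>    sample n_snvs          T      ci_low   ci_high
#> 1 D01_g02     41 0.00000000 0.000000000 0.2376806
#> 2 D01_g04     50 0.05882353 0.001517916 0.2886737
#> 3 D01_g05     46 0.34615385 0.141243570 0.6238847
```

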