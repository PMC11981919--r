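---
title: "Somatic mutation analysis of microdissected gastric glands: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic mutation analysis of microdissected gastric glands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`gastroclone` implements the statistical stages of a gland-resolution somatic
mutation study of gastric epithelium: each laser-capture microdissection (one
gland, or a cluster of glands in targeted panel data) is sequenced at moderate
depth (~23x), and the package takes over after variant calling, from
post-calling filters through burden, signature, copy-number-timing, trisomy
and driver-fraction analyses. Read alignment, primary calling, de-novo
signature extraction, phylogeny reconstruction and selection (dN/dS) analysis
are out of scope; their outputs are inputs here.

Because gland-level sequencing data of this kind sit in controlled-access
archives, the package ships a synthetic cohort generator
(`simulate_cohort()`) that emulates the statistical structure of such a
cohort with known ground truth. All tests and the acceptance script run
against it.

# The generator and what it emulates

A gland is a clonal unit: one stem-cell lineage dominates, so its somatic
variants sit at a common cell fraction and the VAF distribution shows a peak
between ~0.25 and 0.5. The generator draws, per gland:

* a mutation count from a Poisson with mean `rate x age x fold`. The default
  rates are 27.8 SNVs and 2.0 indels per year; metaplastic glands use overall
  folds of 2.8 (SNV) and 4.4 (indel). Poisson is the maximum-entropy choice
  given only a linear rate.
* mutation channels from reference signature profiles. The default SBS mix is
  SBS1 = 0.30, SBS18 = 6/35 and SBS5/40 the remainder, with metaplastic
  accelerations SBS1 x3, SBS18 x8, SBS5/40 x1; the mix was chosen once so the
  accelerations compose exactly to the overall 2.8x fold
  (`0.3*3 + (6/35)*8 + (1 - 0.3 - 6/35)*1 = 2.8`). The indel mix
  (ID1 .4, ID2 .4, ID5 .2 with accelerations 2, 8.5, 1) composes to 4.4x the
  same way and raises the ID2/ID1 ratio in metaplasia.
* a clonal fraction (dominant-clone share of epithelial cells) uniform on
  [0.6, 0.95], with 5% stromal contamination; a diploid heterozygous variant
  is rendered at expected VAF `0.5 x clonal_fraction x (1 - contamination)`,
  i.e. 0.28-0.45, reproducing the observed monoclonal peak range.
* depth from a negative binomial with median 23 (size 30); the mean is solved
  numerically so the distribution's median matches exactly.
* a donor-level multiplicative rate factor, lognormal with mean one
  (`donor_lognorm_sd = 0.1`), standing in for the donor random effect; the
  per-gland variance beyond this is left Poisson, as nothing more specific is
  known.

Germline heterozygous sites are rendered at VAF 0.5 in every sample of a
donor. Stromal cells carry germline variants too, so contamination does not
shift germline VAFs; on a trisomic chromosome the two haplotypes move to
`(1 + f)/(2 + f)` and `1/(2 + f)` for trisomic cell fraction `f` (2/3 and 1/3
in a pure trisomic sample). Recurrent artifacts are low-VAF (0.02-0.10) sites
whose reads scatter near-binomially across all samples of a donor — the
signature the overdispersion filter keys on. Calling is emulated by the
n >= 4 supporting-read rule: variants that never reach 4 reads are not
emitted, which is exactly the censoring the sensitivity correction undoes.

Trisomies (default chr20, probability 0.1 per gland, molecular timing 0.2)
flag pre-gain mutations on the duplicated parental copy: before the gain,
mutations accrue on two copies (each equally likely), after it on three, so
the duplicated fraction of chromosome mutations is `t / (3 - t)` at timing
`t`. Drivers are one disrupting mutation in a selection-positive gastric gene
(probability 0.1 per gland) at the clonal cell fraction.

What the generator does *not* emulate: mapping artifacts with low alignment
scores (ASMD/CLPM are rendered as passing; the quality filter is tested on
constructed records), copy-number landscapes beyond single trisomies,
polyclonal glands, shared embryonic variants between glands, and
site-specific error spectra. Passing tests therefore demonstrate correctness
of the estimators under the stated generative model, not robustness to every
real-data pathology.

# Variant filtering

Three filters apply in a fixed order (`classify_variants()`):
`quality_fail > germline > artifact > pass`; re-running classification is
idempotent.

**Quality.** Median alignment score of supporting reads >= 140 and clipping
median = 0, taken from input columns.

**Germline.** Counts are aggregated across the donor's samples at loci
flagged "largely diploid" (the generator provides the flag; real-data
adapters would derive it from copy-number calls — samples with a gain at the
locus are excluded rather than modelled). The one-sided *lower-tail* exact
binomial p-value against VAF 0.5 is computed: somatic variants are absent
from most samples, depressing the aggregate VAF, so small p is evidence
against germline origin. P-values are BH-adjusted per donor and variants with
q < 1e-5 are called somatic. Loci with no diploid coverage are unassessable
and kept, with a warning.

**Artifact.** For each variant a beta-binomial is fitted to its per-sample
counts with the mean fixed at the pooled VAF and the overdispersion rho
maximized over the grid `log10(rho) = -6, -5.95, ..., -0.05`. Fixing the mean
keeps the search one-dimensional; jointly optimizing the mean is the obvious
alternative but is not what the grid formulation describes. Artifacts scatter
reads near-binomially (low rho); true clonal variants are present at high VAF
in some samples and absent in others (high rho). Thresholds: rho < 0.1
(SNVs) or < 0.15 (indels) = artifact. The C++ kernel searches
coarse-to-fine (every 8th grid point, then refinement around all near-ties
within 0.5 log-likelihood units); the test suite verifies exact agreement
with a dense brute-force grid oracle across thousands of variant patterns.
Degenerate cases: pooled VAF 0 or 1 reports the boundary rho with a flag; a
single informative sample leaves rho undefined and the variant passes this
filter, flagged.

# Clonality, sensitivity, burden

Each sample's passing SNVs are modelled as a binomial mixture truncated at
`min_reads = 4`: component k contributes
`pi_k Binom(nv; nr, p_k) / P(X >= 4; nr, p_k)`. EM with the M-step solved by
safeguarded Newton on the weighted score (the truncation derivative uses
`d/dp P(X <= k; n, p) = -n binom(k; n-1, p)`). K is chosen over {1, 2, 3} by
BIC with 10 random restarts under a fixed seed — small per-sample variant
counts do not support more components. Restarts run 6 exploratory iterations
and the best continues to convergence (absolute tolerance 1e-6, cap 300
iterations; non-convergence returns best-so-far, flagged). For samples with
more than 800 passing SNVs the fit uses an evenly spaced subsample of 800 —
the peak estimate is stable long before that. The observed log-likelihood is
asserted non-decreasing in tests, and at `min_reads = 0` the truncated
likelihood reduces exactly to the plain binomial (also asserted).

Detection sensitivity is
`S = mean_i P(X >= 4 | nr_i, peak)` over the depths at the sample's passing
variant sites, with the peak taken as the largest-weight mixture component.
Using the depths of passing sites (not genome-wide coverage) is the choice
that remains computable from a count matrix; it slightly over-represents
well-covered sites, a bias that is negligible at 23x and VAF > 0.25. The
corrected burden is `raw / S` (S = 0 excludes the sample, flagged). Median
VAF > 0.25 (strictly) calls the gland monoclonal; the boundary itself is
polyclonal, reading "exceeded" literally. Median VAF is computed on
post-filter variants.

Burdens are regressed on age with a donor random intercept
(`Burden ~ Age + (1|Donor)`), fitted by maximum likelihood (not REML) so that
nested fits — adding chronic-inflammation (dichotomized absent/mild vs
moderate/severe) and metaplasia terms, or site-specific age slopes — can be
compared by a likelihood-ratio chi-square, which is how the package reads
"two-sided ANOVA test" for nested mixed models. Observed/expected fold
changes use the fixed-effect prediction at the sample's age from the model
fitted on non-metaplastic glands.

# Signature exposures and folds

Catalogs use the COSMIC channel conventions (96 pyrimidine-centred SBS
channels; 83 ID channels, with 1-bp homopolymer events classified from
type/base/run-length annotations; multi-base events are only length-classed
into repeat catch-all channels — full ID83 classification from a reference
genome is deliberately not attempted, as the indel conclusions rest on
ID1/ID2). Exposures are maximum-likelihood multinomial-mixture weights via EM
(convergence when the log-likelihood moves < 1e-8), verified against a dense
grid search on two-signature problems. Deconvolution of an extracted spectrum
into reference signatures is accepted when the reconstruction's cosine
similarity reaches 0.90. SBS5 and SBS40 (and its split components) are
reported combined as SBS5/40 throughout — their flat profiles are not
reliably separable. Catalogs under 50 mutations warn.

The package ships deterministic *synthetic* reference profiles
(`synthetic_signatures()`), not COSMIC v3.4: they reproduce the features that
matter here (CpG-focused C>T for SBS1, C>A-dominated SBS18, flat mutually
similar SBS5/SBS40a/SBS40c, peaked decoys) in the COSMIC table format, and
`read_signatures()` accepts a real COSMIC TSV wherever one is available.
Signature fitting is per sample; the paper-style per-phylogeny-branch fit is
accommodated by passing externally built branch catalogs.

Per-signature folds in metaplastic glands follow three steps: observed
mutations per signature = exposure x corrected burden; expected = donor
baseline exposure (mean over the donor's non-metaplastic glands) x
age-expected burden; fold = observed/expected. A zero-baseline signature with
non-zero observed count reports an infinite fold, flagged.

# Copy-number-gain timing

SNVs inside a gained region cluster at copy-number-determined VAFs (trisomy:
2/3 duplicated vs 1/3 non-duplicated, scaled by the trisomic cell fraction).
The cluster means are *fixed* at those expected VAFs — with tens to hundreds
of SNVs per gland, free means are not identifiable — and only the mixing
weights are estimated; each SNV is assigned by posterior responsibility, ties
conservatively to non-duplicated. The timing is
`T = CN_total / (CN_dup + P_ND / P_D)`, clamped to [0, 1] with a flag when
sampling noise pushes it above 1. The 95% interval treats the rounded cluster
counts as Poisson: conditional on the total, the non-duplicated count is
binomial, so the Clopper-Pearson bounds for the non-duplicated fraction are
transformed through the timing formula (equivalent to the exact Poisson
ratio test). `cnv_age_estimate()` converts T to an approximate age as
`T x corrected burden / fitted rate` — an interpretation: without phylogenies
T strictly spans the sample's whole mutation time, so the conversion is an
upper-bound-flavoured approximation.

# Panel trisomy detection

Heterozygous chromosome-20 SNPs are phased from trisomic WGS samples: VAF >
0.5 marks the duplicated haplotype; samples duplicating opposite parental
copies are harmonized by orientation flip against the first sample, and a
majority vote with a concordance statistic summarizes agreement. In each
panel sample, sites with more than five reads (nr >= 6) enter a
likelihood-ratio test of one shared binomial (null probability = pooled-count
MLE over both haplotype groups; a per-site-mean alternative is available
behind a flag) against per-haplotype binomials, referred to chi-square with
1 df — the natural reference distribution, which the source text does not
state. P-values are BH-adjusted across the donor's panel samples; a call
requires q < 0.05 (the significance level is also unstated upstream and is
configurable) *and* a haplotype mean-VAF difference >= 0.1. Site enrichment
uses an exact r x c Fisher test implemented by full enumeration of
margin-consistent tables (all-zero rows/columns dropped; p = total
probability of tables no more likely than observed), cross-checked against
`fisher.test` in the suite.

# Driver-mutant epithelium fraction

A driver's clone fraction is `min(1, VAF x local ploidy)` (ploidy 1 for sex
chromosomes in male donors). Multiple drivers in one microdissection combine
by the maximum (clones assumed nested/overlapping) — the conservative
reading; a capped-sum alternative sits behind a flag. The cohort estimate is
the area-weighted mean mutant fraction, invariant to splitting a
microdissection and non-decreasing in any VAF; driver-free contaminant reads
only depress it. Regressions of the proportion on age, chronic-inflammation
grade and metaplasia proportion run at donor level (one value per donor) to
avoid pseudo-replication — the aggregation unit is a genuine open choice.

# Problem sizes and numerical choices

The acceptance workloads simulate 20 replicate cohorts of 12 donors x 7
glands (ages uniform 25-80) plus 19 metaplastic glands — enough that the
mean recovered SNV slope has a Monte-Carlo standard error near 1 mutation/yr
while a full run stays comfortable on a laptop core. Property simulations use
100-500 replicates of cheap statistics (timing intervals, LRT calls). Other
fixed numerics: EM tolerances 1e-6 (VAF mixture, absolute) and 1e-8
(exposures); rho grid as stated; probability floors at 1e-300 to avoid log
underflow; upper-tail binomial computed directly (never 1 minus the lower
tail) to avoid catastrophic cancellation at small p.

# Known limitations

* The generator's monoclonal glands make the VAF mixture's K selection easy;
  K > 1 behaviour is exercised on constructed mixtures rather than cohorts.
* Sensitivity correction assumes the fitted peak applies to all passing
  variants of the sample; subclonal variants in real glands violate this
  mildly.
* Synthetic signature profiles share channel conventions but not the exact
  COSMIC shapes; exposure *values* on real catalogs require real reference
  tables via `read_signatures()`.
* The per-sample timing-to-age conversion ignores phylogenetic branch
  structure.
* The panel stage emulates site-to-trisomy enrichment generically; it is a
  harness for the detector, not a model of any particular stomach.
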