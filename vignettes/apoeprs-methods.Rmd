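---
title: "apoeprs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{apoeprs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it
implements: the data-generating model behind the synthetic cohorts, the
analysis pipeline stage by stage, the parameters that matter with their
defaults and units, the numerical conventions, and the limits of what a
green test establishes. It states no empirical result that the test
suite does not itself compute.

## 1. The analysis in one paragraph

A polygenic risk score (PRS) is built from discovery GWAS summary
statistics: SNPs are quality-filtered (imputation Info ≥ 0.8, MAF ≥
0.01), hard-called at the 90% most-probable-genotype rule, LD-pruned
greedily in p-value order (r² ≤ 0.1 within 500 kb), and summed as
`Σ β·dosage` over SNPs with discovery p ≤ t (t = 0.5 for the headline
model). Scores are z-standardized and residualized on two ancestry
principal components. Discrimination is measured per APOE stratum
(whole cohort, E4 carriers, E4-or-E2 carriers, E3 homozygotes) by
Mann–Whitney AUC with DeLong 95% intervals, with and without the APOE
region's SNPs. Two companion analyses probe the result: a
risk-vs-alternative allele-burden comparison between E3 homozygotes and
the other genotypes, and a simulation-based correction for
discovery/test sample overlap that redraws each beta as
`N(β, c·SE)`, c = 0.12, and averages AUC over 1000 re-scorings.

## 2. The synthetic cohort model

The generator (`sim_config()`, `simulate_cohort()`,
`simulate_discovery_sumstats()`) is a first-class, tested module. It
emulates the *statistical structure* the pipeline assumes, not human
genetics per se.

**Haplotypes and LD.** Each background SNP has an alleleB frequency
drawn uniformly from `maf_range` (default 0.05–0.5). Haplotypes come
from a Gaussian copula: a latent standard normal follows an AR(1)
process with correlation `ld_rho` (default 0.6) inside blocks of
`ld_block_size` SNPs (default 10) and is independent across blocks; the
allele is carried when the latent value falls below the frequency
quantile. This is the simplest mechanism that yields tunable pairwise
r² for the pruning stage while keeping blocks exactly independent —
there is no recombination map, no allele-frequency spectrum, no
population history. Blocks are laid out round-robin over 22 autosomes,
SNPs 25 kb apart and blocks 1 Mb apart, so the 500 kb pruning window
binds within blocks but not between them.

**The APOE locus.** Each person draws two APOE alleles from
`apoe_freqs` (default E2 = 0.08, E3 = 0.77, E4 = 0.15, approximately
European frequencies), giving Hardy–Weinberg genotype proportions. The
locus is emitted twice: as a genotype label on the sample table and as
two biallelic tag SNPs placed inside the APOE region on chromosome 19 —
rs429358 (C allele counts E4 copies) and rs7412 (T allele counts E2
copies) — so the region-exclusion and classification code paths are
exercised on realistic coordinates.

**Disease model.** Case/control status is logistic on the log-odds
scale: `η = intercept + Σ β_j g_ij + APOE offset`, with `n_causal`
background SNPs (default 50) carrying effects `N(0, effect_sd²)`
(default sd 0.15) and per-allele APOE offsets `apoe_betas` (default
E4 = +1.2, E2 = −0.5 — log odds ratios of ≈3.3 and ≈0.6, in the range
reported for ε4 and ε2). The intercept defaults to `qlogis(0.15)`, a
15% population prevalence plausible for an elderly sampling frame. The
source study states neither its cohort's prevalence nor its effect-size
distribution, so these defaults were chosen once for testability —
enough signal that stratified AUCs are meaningfully above chance at
n ≈ 1500 — and are not revisited. Case and control quotas are filled by
rejection sampling from the population (capped at 500× the cohort size,
with an explicit error naming the bound), mirroring case-control
ascertainment. Sex is Bernoulli(0.5) with zero true effect; it exists
so covariate adjustment is exercised.

**Imputation blur.** True genotypes are emitted as probability triples:
a mixture `(1−w)·indicator + w·Dirichlet`, where the Dirichlet is
centred on the SNP's Hardy–Weinberg probabilities (concentration 50)
and `w = 1 − √t` targets an IMPUTE-style Info score t drawn from
`info_range` (default 0.85–1). Info is then *measured* on the emitted
triples as observed/expected dosage variance and stored in the
metadata; because the blur is stochastic the realized Info scatters
around the target (the tests assert a loose band), and values
marginally above 1 are kept, capped at 1.05, as real imputation output
does.

**Discovery summary statistics.** A discovery sample of `discovery_n`
(default 4000) is drawn from the same world; with
`overlap_fraction > 0` that fraction of the test cohort is re-used
verbatim — the mechanism that reproduces overlap inflation.
Association is per-SNP logistic regression of status on the true
(unblurred) dosage without covariates: the discovery GWAS emulates a
large consortium analysis whose covariate structure is irrelevant to
the downstream contracts. Monomorphic SNPs get NA SE/p and are excluded
downstream.

**What a green test does not establish.** The generator has no real LD
map, no strand ambiguity (unless asked), no relatedness, no batch
effects, and only a toy two-population structure in the PCA tests.
Green acceptance means the *methods* are implemented correctly under
the stated model; it says nothing about predictive accuracy on real
cohorts.

## 3. Pipeline conventions and numerical choices

* **Hard-calling** uses strict inequality (`> 0.9`), reading "over 90%"
  literally; ties at the maximum only matter below the threshold.
* **MAF** is computed from expected (fractional) dosages *before*
  hard-calling, the imputation-era convention; QC boundaries are kept
  (Info = 0.8 and MAF = 0.01 pass).
* **Pruning** measures r² on the test cohort's own hard calls over
  jointly non-missing samples (no external LD reference); zero-variance
  SNPs define r² = 0 with a warning. Ties in p are broken by
  chromosome, then position, then SNP id, making the output invariant
  to input row order. The window is inclusive: `|Δpos| ≤ 500000`.
* **Allele alignment**: effect/other vs alleleA/alleleB, sign −1 when
  swapped (dosage 2−g); palindromic A/T and C/G SNPs are dropped by
  default (the generator never emits them unless configured, so the
  policy is testable but not load-bearing).
* **Missing dosages** in scoring default to the SNP's mean aligned
  dosage (`mean_dosage`), which leaves the score unbiased under missing
  at random; `omit` is available for sensitivity checks.
* **Standardization** is pooled over cases and controls; strata are
  restandardized after subsetting (for tail counts). AUC is invariant
  to both choices, so they affect only descriptive output.
* **APOE region** defaults to chr19:44,400,000–46,500,000 (inclusive),
  a configuration value: the source analysis names no coordinates, and
  this window generously covers APOE and its neighbours on GRCh37.
* **Logistic fits** (association scan and predictor) are IRLS via
  `glm.fit`, 25 iterations, tolerance 1e-8; Wald statistics. A score
  test would match snptest's default more closely, but Wald estimates
  admit a closed-form 2×2 oracle, which the tests exploit; this is a
  documented deviation. Separation is flagged (|β| > 15 or
  non-convergence) and flagged SNPs are excluded with a logged count.
* **PCA** imputes missing calls to the SNP mean, standardizes columns,
  and fixes signs by making each component's largest-magnitude loading
  positive. The pipeline computes PCs on the pruned SNP set *excluding
  the APOE region* — pruning avoids LD-driven axes, and the exclusion
  keeps the covariate orthogonal to the signal that the stratified
  analyses condition on.
* **DeLong intervals** use the midrank formulation of the structural
  components (exact under ties, O(n log n)); degenerate AUCs of 0 or 1
  collapse the interval to a point with a warning. Bootstrap is
  deliberately not the default: determinism and speed.
* **Overlap adjustment** freezes the retained, thresholded SNP set
  before perturbing: the correction perturbs *effect sizes*, not SNP
  selection (re-selection is available behind a flag; with noise on
  betas only, p-values never change, so it is inert by default).
  Perturbations are independent across SNPs; the calibration of
  c = 0.12 from consortium sample counts is out of scope — c is
  configuration. Replicate scores are restandardized, which leaves AUC
  unchanged; the choice is benign and made for symmetry with the main
  pipeline.
* **Determinism**: every stochastic stage takes an explicit integer
  seed; pipeline outputs contain no timestamps and are byte-identical
  across reruns with the same config (asserted in the tests).

## 4. The allele-burden test and its calibration

The burden analysis counts, per person, risk alleles (the allele with
positive aligned discovery beta) and alternative alleles over the SNPs
passing each p-value threshold, excluding the APOE region, and compares
E3 homozygotes with all other determinate genotypes — separately in
cases and controls, since cases carry more risk alleles overall. The
2×2 summary `{(risk, alt) × (stratum A, B)}` is reported as printed in
threshold-profile tables: *mean counts per person*, with the
cross-product odds ratio and a Pearson chi-square without continuity
correction.

A caution that the package makes explicit rather than hiding: the
chi-square on the *means* table is not a calibrated test. The statistic
treats each cell as a Poisson-scale count, but the variance of a mean
over n ≈ 600 people is the per-person variance divided by n — two to
three orders of magnitude smaller than the statistic assumes — so
p-values pile up near 1 and the test essentially never rejects. This
matches the uniformly non-significant p-values such tables print. For
any question where calibration matters, `use_totals = TRUE` builds the
table from summed allele counts, which are genuine counts; even then
the test is mildly conservative in this package's synthetic world,
because allele-frequency heterogeneity makes the true Bernoulli-trial
variance `Σ 2p_j q_j` smaller than the pooled `2m·p̄q̄` the chi-square
assumes, with block-LD compensating only partly. The acceptance suite
measures exactly this: mean null AUC sits in [0.47, 0.53], and the
totals-based rejection rate at α = 0.05 lands just below the 95%
binomial band (0.032 against a lower bound of 0.037 in the frozen run)
— reported honestly as a near-miss property of the Pearson
approximation under heterogeneity, not patched by tuning the generator
or the band.

## 5. Known limitations

* Scoring is hard-call based; fractional-dosage scoring and shrinkage
  weights (LDpred-style) are out of scope.
* ROC scores are in-sample fitted values — optimistic by construction;
  there is no cross-validation.
* The double-heterozygote APOE call (one ε4-tag and one ε2-tag allele)
  is genuinely phase-ambiguous from dosages and is reported
  indeterminate, then excluded from stratified analyses with a logged
  count; no phasing is attempted.
* The GEN/SAMPLE dialect is the space-delimited Oxford flavour without
  chromosome-column variants; BGEN, multi-allelic sites and chromosome
  X conventions are not supported.
* `theoretical_auc()` assumes equal-variance normal scores; with strong
  single-locus effects (APOE in), score distributions are mixtures and
  the closed form is only an approximation — the acceptance check
  therefore uses a purely polygenic configuration.
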