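---
title: "Methods: from genotypes and two-tissue expression to candidate taint markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from genotypes and two-tissue expression to candidate taint markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taintQTL)
```

`taintQTL` maps expression quantitative trait loci (eQTLs) in porcine liver
and testis, filters them by association with summarised estimated breeding
values (EBVs) for boar-taint indicators (skatole concentration and human nose
score), and selects candidate marker genotypes carried by low-EBV animals.
This vignette documents the models, the tunable parameters, the
synthetic-data generator and its limits, the numerical choices, and the open
design decisions this package resolved.

## 1. Variant quality control

Genotypes are allele dosages in {0, 1, 2} with explicit missingness, coded on
the minor (B) allele at load time. Four filters run in a fixed order — call
rate, Hardy–Weinberg, minor allele frequency, LD pruning — and each removed
variant is attributed to the *first* filter it fails, so the report counts
always balance. (Published removal counts from chained PLINK runs need not
balance because a variant can fail several filters; attribution-to-first is
this package's bookkeeping convention.)

* **Call rate** > 0.95, strict: non-missing fraction per variant.
* **Hardy–Weinberg**: the exact conditional test. Given `n` genotypes and
  `n_B` minor-allele copies, the probability of each attainable heterozygote
  count `h` (same parity as `n_B`) follows
  `P(h) ∝ n! n_B! (2n−n_B)! 2^h / (n_AA! h! n_BB! (2n)!)`, computed by the
  standard log-recurrence. The two-sided p-value sums all configurations no
  more probable than the observed one (with a 1 + 1e-10 relative slack for
  ties); variants with p ≤ 1e-4 are removed. Mid-p variants of the test are
  not used.
* **MAF** > 0.05, strict, over non-missing calls.
* **LD pruning**: per chromosome, a window of 5 kb advancing in 5 kb steps;
  within a window every still-retained pair with dosage r² > 0.8 loses its
  lower-MAF member (tie: the later-position variant). Greedy left-to-right
  and deterministic; re-pruning the output removes nothing. Zero-variance
  columns define r² = 0 (nothing prunable).

## 2. Expression preparation

Genes with mean raw count strictly greater than 5 (per tissue) are kept.
Library sizes are the column sums of the *filtered* matrix; normalised values
are `log2((count + 0.5) / (libsize + 1) × 1e6)`. Precision weights follow the
voom recipe in simplified form: per-gene OLS residual standard deviations
`s_g` on the supplied design, a lowess trend (span 0.5) of `sqrt(s_g)`
against mean log-expression, piecewise-linear interpolation of the trend at
each observation's fitted value, and weight = trend⁻⁴, clipped to
[1e-6, 1e6]. Array-quality weight *estimation* is out of scope; per-sample
weights may be supplied and are multiplied in. The trend is floored at 1e-3
before inversion so a degenerate smoother cannot produce infinite weights.
The scan itself is unweighted by default (`use_weights_in_scan = FALSE`),
matching the standard mode of matrix-based eQTL scanners.

## 3. The cis/trans scan

With covariates X (intercept plus indicators for the medium/high EBV groups),
both the expression matrix and the dosage matrix are row-wise replaced by
least-squares residuals against X (via one QR decomposition), rows are scaled
to unit norm (zero-variance rows dropped with a warning), and all gene–SNP
correlations are computed blockwise as a matrix product. Then
`t = r sqrt(df/(1−r²))` with `df = n − rank(X) − 1`, two-sided p from the t
distribution; r is clipped to ±(1 − 1e-12) before the transform. This is
algebraically identical to the slope t-test of `expression ~ dosage + X`
(asserted against that oracle to 1e-8 in the tests).

A pair is **cis** when the SNP lies within 1 Mb of the *gene body*
(`[start − 1 Mb, end + 1 Mb]`); the reported distance is `SNP pos − gene
start`, negative upstream. Anchoring the window on the body while reporting
start-anchored distances reproduces the published convention in which a few
cis distances slightly exceed 1 Mb. Pairs are retained at p < 1e-3 (cis) and
p < 1e-6 (trans); BH FDR is computed separately per tissue × class with `m`
equal to the number of tests performed, not the number retained (on retained
sets this is a slightly conservative upper bound of full-family BH; with
`keep_all = TRUE` it is exact). Significance means FDR < 0.05. All pairs
passing the p thresholds are kept in the output with their FDR flag, since
FDR-level truncation at scan time is not possible when only extreme pairs
are stored.

## 4. EBV and expression association ("filtered eQTLs")

For each retained eQTL, samples group naturally by genotype class. Two
nested-model F tests compare `response ~ covariates` against
`response ~ covariates + genotype factor`, with response (i) the summarised
EBV and (ii) the gene's normalised expression; covariates are tissue yield
(mg), a genotyping QC metric, and RIN. The original description says the
covariates entered as *interacting* covariates; with n = 48 and a 3-level
factor a full interaction model is barely identifiable, so the default is
additive, and `interactions = TRUE` adds covariate × genotype terms for users
who want the literal reading. Degenerate cases are explicit: one non-empty
class gives p = 1 with a warning; an exactly-fitting full model gives p = 0
with a `degenerate` flag; a constant response gives F = 0, p = 1. BH runs per
tissue and per test family, pooled across cis and trans; records with both
FDRs < 0.05 are the *filtered eQTLs*.

## 5. The multi-tissue mixture model

Scan t-statistics are mapped to z-scores by the probability-preserving
transform `|z| = Φ⁻¹(1 − p/2)` with the sign of t, computed in log space so
|t| of any size stays finite. Rows of the z-matrix are the union of pairs
passing either tissue's p threshold *and measured in both tissues*; the
partner tissue's statistic is recomputed for rows it did not retain (no
censoring at the threshold). Whether the original analysis fed all pairs or
only scan-passers into its multi-tissue stage is not documented; the union
rule is this package's recorded choice.

Each row follows a mixture over activity configurations γ ∈ {0,1}^T (T = 2):
`z | γ ~ N(0, Σ_γ)`, `Σ_γ = Δ + D_γ Σ D_γ`, with Δ the null covariance (unit
diagonal, off-diagonal ρ₀) and Σ the signal covariance. ρ₀ is estimated once
by Pearson correlation over rows with max |z| < 1 and then fixed. EM fits the
weights p_γ and Σ: responsibilities in the E-step; weights by mean
responsibility (exact EM); Σ by responsibility-weighted moment matching on
the all-active component (`Σ = S₁₁ − Δ`), with sub-block inheritance for
partial configurations. Because the moment step is not exact EM, a candidate
update is accepted only if it does not decrease the log-likelihood (otherwise
only the weight update is applied), so the reported trace is monotone by
construction. Σ's eigenvalues are floored at 0.25: a signal component must
explain at least a quarter z²-unit of extra variance, otherwise it collapses
onto the null and the null weight leaks into arbitrary partial
configurations (visible as p₀₀ ≪ 1 on pure-null data without the floor).
Convergence: log-likelihood gain < 1e-6, at most 500 iterations; the seed
only randomises the weight initialisation.

Calls rank pairs by the local false discovery rate of the all-active
configuration, `lfdr = 1 − P(γ = 11 | z)`; the call set is the largest
lfdr-ordered prefix whose mean lfdr (its estimated global FDR) stays ≤ 0.05.
On data simulated from the model the realised false-discovery proportion at
target 0.05 stays below 0.08 over 20 replicates (tested). Note that when the
z-matrix is built from scan-retained pairs the fitted p₀₀ is legitimately
near 0 — that input is signal-enriched by construction.

## 6. Genomic statistics

Chromosomal density is eQTL count over chromosome length, times a reporting
scale (default 1e8). Published density figures carry an unstated scale, so
absolute reproduction is not attempted; ordering is scale-invariant. The
co-expression network uses Spearman rank correlation (midranks for ties)
between multi-tissue eQTL genes within each tissue. The published threshold
"R² ≥ 0.5 or below R² < −0.5" cannot describe a squared quantity; it is read
here as |ρ| ≥ 0.5 on the signed coefficient, with the sign as the edge class.
Both tissues' edges are emitted with a tissue column.

## 7. Trait-QTL enrichment

The trait-QTL table keeps only breeds carrying ≥ 1000 QTLs in the input
table. For each trait, intervals are merged per chromosome before the length
sum (preventing π > 1 and double counting; `merge = FALSE` gives the
paper-literal plain sum), and π = L_trait / G with G defaulting to the 2.7 Gb
porcine background. The SNP set of the filtered cis eQTLs is deduplicated — a
SNP shared by several eQTLs is one trial — and k counts SNPs inside ≥ 1
interval (inclusive ends, once per trait). The test is the one-sided upper
binomial tail `P(X ≥ k)`, k = 0 giving p = 1; BH across all tested traits;
enriched means FDR < 0.05. The category summary divides enriched-trait counts
by the database-wide category totals and reports three decimals (exact value
retained).

## 8. Candidate selection

A filtered cis eQTL becomes a candidate when (i) some genotype class has a
median summarised EBV ≤ EBV_max, with the exact configured default
−0.0699208 (the printed low-group maximum; the rounded −0.070 appears in
prose), inclusive per "equal to or lower than"; and (ii) its SNP overlaps an
*enriched* boar-taint trait (default names: "Fat androstenone level",
"indole, laboratory", "Off-Flavor Score", "Overall impression, sensory
panel"). One output row per (eQTL, qualifying genotype, overlapped trait);
records of the same SNP–gene pair found in both tissues merge with tissue
"both" and the smaller fdr_ebv. Bookkeeping reports unique SNP–gene pairs,
unique genes and unique genotype triples separately, because one eQTL can
contribute several candidate genotypes and overlap several traits.

## 9. The synthetic-data generator

The generator states the emulated world; its defaults are the study's stated
conditions and are not tuned against test outcomes.

* **Design**: 48 animals, EBV groups 16/16/16; 20,827 variants and
  10,545/12,731 genes by default (tests scale these down explicitly); MAF in
  (0.05, 0.5].
* **Genotypes**: positions uniform per chromosome on an approximate pig
  autosome+X genome (~2.6 Gb; synthetic convenience lengths). One MAF per
  50 kb LD block shared by its variants; haplotypes by Markov copying
  (probability 0.9 of copying the previous variant's allele within a block),
  which tunes adjacent r² while leaving every variant exactly at its drawn
  marginal MAF and in Hardy–Weinberg proportion.
* **Expression**: negative binomial with log link (standard for bulk
  RNA-Seq; the source data's distribution is not stated), log-normal gene
  baselines, library factors in [0.7, 1.3], dispersion 0.1; planted pairs
  shift the log2 mean by dosage × effect (default 1.0 log2-unit, 50 cis and
  10 trans pairs).
* **EBVs**: linear in dosage plus Gaussian noise. True EBVs come from a
  national evaluation and are unreproducible; only their structure is
  emulated. By default the causal variants are drawn among the planted cis
  SNPs (genetic merit mediated by regulatory variation) so the filtered-eQTL
  stage has a true positive path; groups are EBV tertiles. The published
  asymmetric group means (0.71/−0.01/−0.38) arise from selecting 48 of 114
  animals (extremes plus middle); setting `n_pool = 114` emulates that
  selection, and the generator reports realised group means ± sd rather than
  promising the printed values. Covariates (RIN, yield, genotyping QC) are
  independent of EBV.
* **Trait database**: 100 traits, ~30 QTLs each (Poisson), log-normal
  interval lengths around 4 Mb (trait-QTL intervals are characteristically
  huge), categories from the five standard ones, breeds Duroc/Landrace/
  Pietrain weighted 5/4/1 so the ≥ 1000-QTL breed filter passes the major
  breeds and drops the minor one at default size; the four boar-taint trait
  names are always present.

What a green test does *not* establish: the generator has no population
structure or relatedness (the real animals share sires), no pedigree-based
EBV shrinkage, no sequencing batch effects, and LD only within blocks.
Headline counts of the motivating study (205/109 filtered eQTLs, 26
multi-tissue eQTLs, 89 enriched traits) depend on unavailable animal data
and a live database snapshot and are consequently not acceptance targets;
the tests instead assert arithmetic replays of the printed tables, oracle
equivalence of every statistic, and calibration/recovery on the synthetic
world.

## 10. Numerical choices and degenerate inputs

* HWE tie tolerance 1 + 1e-10; probabilities by log-recurrence (stable to
  n = thousands).
* r clipped to ±(1 − 1e-12) before the t transform; zero-variance rows
  dropped from the scan with a warning.
* t→z in log space (`qnorm(pt(−|t|, df, log = TRUE), log = TRUE)`), finite
  for any t.
* EM: tol 1e-6 on the log-likelihood, max 500 iterations, non-convergence
  returned with a flag rather than an error; Σ eigenvalue floor 0.25; ρ₀
  clipped to ±0.95 and needing ≥ 10 clearly-null rows (else 0).
* BH implemented explicitly (step-up with cummin), identical to
  `p.adjust(·, "BH")` and shared by every stage.
* Empty QC output is a warning, not an error; an empty intersection of
  tissue pairs is an error for the multi-tissue stage (the pipeline driver
  downgrades it to a warning and skips the stage).
* Config serialisation is JSON (no YAML parser among the declared
  dependencies); round trip is lossless and tested.

## 11. Known limitations

* The EBV association is a fixed-effects F test; no polygenic/mixed-model
  control, matching the emulated analysis but anti-conservative under strong
  relatedness.
* BH across scan output retained at p thresholds upper-bounds full-family
  BH slightly (exact in `keep_all` mode).
* The enrichment test treats SNPs as independent trials; LD between filtered
  SNPs inflates significance, as in the emulated analysis.
* T = 2 tissues is the tested configuration; the mixture code is generic in
  T but degenerate-covariance pooling for large T is not optimised.
* VCF input requires VariantAnnotation and accepts biallelic records only.
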