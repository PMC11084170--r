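---
title: "Methylation-heterogeneity age clocks: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-heterogeneity age clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wshclock)
```

## The problem

Bulk bisulfite sequencing (RRBS/WGBS) yields, for every sequenced DNA
molecule, an ordered string of binary methylation calls over the CpGs the
read covers. Most epigenetic age (eAge) clocks collapse this to per-CpG
average methylation and regress age on it. That aggregation discards the
*within-sample heterogeneity* (WSH) of methylation patterns — the
molecule-to-molecule disorder that grows with cell-type drift,
allele-specific methylation and stochastic methylation erosion during
aging. `wshclock` builds age predictors from that discarded signal and
compares them with conventional region-methylation clocks.

## The five WSH scores

All scores are computed per *heterogeneity locus* from the reads of one
sample. The locus unit is one CpG site, except epipolymorphism, whose unit
is four consecutive covered CpGs. For reads $r$ covering the anchor:

* **PDR** (proportion of discordant reads): a read is discordant if it
  carries both an M and a U call; PDR is the discordant fraction among
  reads with at least `pdr_min_cpgs_per_read` (default 4) calls. Captures
  methylation erosion within molecules.
* **PM** (epipolymorphism): $1 - \sum_{k=1}^{16} p_k^2$ over the empirical
  frequencies $p_k$ of the 16 possible 4-CpG epialleles. Maximum
  $1 - 1/16 = 0.9375$ at the uniform epiallele distribution.
* **MHL** (methylation haplotype load):
  $\sum_l l\,M_l \,/\, \sum_l l$, where $M_l$ is the fraction of
  fully methylated contiguous call substrings of length $l$ across the
  covering reads, summed over lengths observed at least once. Equals 1 iff
  every covering read is fully methylated, 0 when nothing is. Substrings
  never bridge two reads.
* **FDRP**: over all unordered pairs of covering reads (deterministically
  subsampled to `fdrp_max_reads`, default 40), the fraction of pairs
  differing at one or more shared CpGs within `fdrp_window_bp` (default
  50 bp) of the anchor.
* **qFDRP**: same pairs, but each contributes its normalised Hamming
  distance (differing / shared CpGs). Hence qFDRP ≤ FDRP everywhere.

`min_depth` (default 10) reads are required to emit any score; shallower
loci are `NA`, never 0 — zero is a meaningful score. These defaults follow
the reference WSH tooling conventions; the upstream publications fix the
estimators, not the thresholds, so all are configurable in
`metric_params()`.

MHL is anchored per CpG (reads spanning that CpG), matching the convention
that the measurement unit of MHL/PDR/FDRP/qFDRP is a single CpG site,
rather than the predefined haplotype blocks of the original MHL
formulation. PM quartets are overlapping runs of four consecutive covered
CpGs with no genomic distance cap (none is stated upstream; loci in the
simulator span ≤ 100 bp, where a cap would be inert).

## Clock construction

1. **Age association.** Each locus's score vector is correlated with donor
   age (Spearman, midranks, pairwise-complete, ≥ 3 pairs). p-values are
   BH-adjusted within each metric's locus universe (each metric has its own
   feature space, so FDR control is per-universe). Three subsets are
   formed: negative (ρ ≤ −0.25), positive (ρ ≥ 0.25), and high
   (|ρ| ≥ 0.5), all additionally requiring adjusted p < 0.05. The |ρ| and
   p filters are applied as a conjunction.
2. **WSH clock.** A regression random forest is fitted on the `high`
   subset: 80/20 train/test split; hyperparameters (trees {200, 500},
   depth {∞, 5, 10}, minimum leaf {1, 3, 5}) chosen by 5-fold
   cross-validated MAE on the training split; stability estimated by 5
   repeats of 10-fold CV at the chosen hyperparameters; final fit on the
   full training split, evaluated once on the untouched test split.
   Missing scores are imputed with per-feature *training* medians, so the
   test split never informs any fitted quantity.
3. **Region clock.** The genome (sex chromosomes and mitochondrion
   excluded) is segmented by 14 schemes: fixed bins of 9000…100 bp and a
   100 bp sliding window with 20 bp step. Per window and sample, CpGs with
   coverage < 5 are dropped and the value is the call-weighted methylation
   proportion Σmeth/Σ(meth+unmeth); windows undetermined in any sample are
   removed, identical rows deduplicated (first in genomic order kept).
   Windows pass a Pearson filter (|r| ≥ 0.5, BH p < 0.05) and feed a LASSO
   whose penalty is selected by 10-fold CV on the training split
   (log-spaced path, MAE loss). Both out-of-fold CV performance and
   train-refit performance are reported, since either reading of
   "cross-validation performance" occurs in practice.
4. **Minimisation.** Recursive feature elimination from the LASSO's
   non-zero windows: refit at a fixed penalty, drop the feature with the
   smallest standardised coefficient magnitude, re-evaluate on the fixed
   test split, down to one feature. The minimal clock is found by a
   contiguous stopping rule: features are removed while test MAE stays
   within 5% (configurable) of the full model's, and the minimal set is
   the one reached just before the first violation. An isolated
   smaller-k dip back under the bound does not count — once accuracy has
   been compromised, a lucky noise excursion is not a valid panel, which
   is also what the dashed "minimum number of loci" line on an RFE curve
   denotes.
5. **Reciprocal filtering.** Two combined pipelines restrict WSH loci to
   age-correlated windows (any-overlap, logged) or windows to those
   overlapping high-|ρ| loci, then refit the corresponding clock.

## The synthetic cohort

The generator states a world resembling a human blood RRBS aging cohort
and is itself first-class, tested code. Defaults: 180 donors, ages uniform
on 19–56 years; 50 + 50 heterogeneity loci with increasing/decreasing
disorder, 50 mean-methylation drift loci, 500 null loci; 6 CpGs per locus
15 bp apart, loci 2 kb apart on two toy chromosomes; reads span 4–6 CpGs
with negative-binomial depth (mean 30, size 8).

Heterogeneity loci emit coherent haplotypes — all-M with per-locus
probability $p \sim U(0.3, 0.7)$, else all-U — whose calls are then
flipped independently with probability
$\varepsilon(a) = \mathrm{clamp}(0.05 + 0.25a - 0.10a^2,\ 0,\ 0.5)$
($a$ = min–max normalised age; decreasing loci use $1-a$). One dial
therefore raises PDR, PM, FDRP and qFDRP and lowers MHL simultaneously,
and its concave-increasing shape reproduces the fast-young/slow-old
quadratic global trend that `mean_score_trend()` fits. Drift loci draw
per-call Bernoulli states with logit-linear age link (μ0 = −1, |γ| = 2,
alternating sign), moving average methylation from ≈ 0.27 to ≈ 0.73 across
the age range — the signal a region clock needs. Null loci use the
age-constant ε(0). Ages are uniform rather than right-skewed like real
blood cohorts; uniform ages maximise correlation-test power at desk-scale
n, and a skew would only shrink effective sample size.

What a green test does *not* establish: the simulator has no fragment-end
bias, no bisulfite conversion failure, no SNPs, no cell-composition
covariance between loci, and its planted effects are far stronger than the
|ρ| ≈ 0.5 loci of real blood data. Recovery tests validate the machinery
(scoring, selection, model fitting), not the biological effect sizes; the
printed performance of the original blood-cohort analysis is explicitly
not reproducible without the 182-sample accession and is out of scope.

## Numerical and design choices

* **Random forest**: no regression-forest package exists in the pinned
  environment, so the package ships a compact CART forest (Rcpp):
  variance-reduction splits, midpoint thresholds between distinct values,
  bootstrap per tree, per-node feature subsampling, impurity importances.
  `mtry` defaults to ⌊√p⌋ (the planted `high` sets hold hundreds of
  anchors; all-feature search is ~10× slower with no measured accuracy
  gain). Deterministic given a seed (std::mt19937, independent of R's
  RNG). Predictions are leaf-mean averages, hence bounded by the training
  age range.
* **Spearman p-values**: t-approximation; exact permutation enumeration
  only for n ≤ 7 (beyond that, enumeration is not desk-scale). Constant
  score vectors are skipped with the locus dropped from the record, not
  given ρ = 0.
* **FDRP subsampling**: deterministic per anchor (seed combined with the
  anchor position), so reruns are bit-identical; tests and acceptance runs
  disable subsampling when comparing against the pair-enumeration oracle.
* **Bismark dialects**: both start = end point records and 1-based
  inclusive intervals are accepted; the writer emits the point dialect.
  Strand is assumed already collapsed to the forward-strand C, as in
  strand-merged coverage workflows; no strand field is carried.
* **Coordinates**: windows are 0-based half-open (BED), CpGs 1-based
  (Bismark); CpG p lies in window [s, e) iff p − 1 ∈ [s, e). Trailing
  partial windows are kept at segmentation (CpG-content filters remove
  empty ones later); sliding windows are truncated at chromosome ends
  rather than discarded, and the choice is inert for interior loci.
* **Window values** are call-weighted (Σmeth/Σcalls), the standard
  downstream aggregation and the robust choice at low coverage; the
  unweighted per-CpG mean is available behind `per_cpg_mean = TRUE`.
* **R²** is reported as the coefficient of determination
  1 − SS_res/SS_tot; the squared Pearson correlation is emitted alongside
  (`r2_cor`) because the convention differs between toolchains.
* **Score matrices** are serialized with `%.17g`, so write→read
  round-trips are bit-identical including `NA` cells.

## Known limitations

* FDRP/qFDRP scoring iterates anchors in R with matrix pair-enumeration;
  it is fast enough for desk-scale cohorts (~1 min for 180 samples × 650
  loci) but would want a compiled kernel for millions of CpGs.
* The CLI covers simulate/score/correlate/windows/run-all; model
  subcommands are reachable through the R API.
* The exact-permutation Spearman path is only engaged for n ≤ 7; for 8–10
  samples the t-approximation is used even though the upstream convention
  is ambiguous there.
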