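---
title: "Methods: screening splicing factors for pan-cancer silencing and its microexon consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening splicing factors for pan-cancer silencing and its microexon consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mexscreen)
```

## The problem

Microexons — cassette exons 3 to 27 nucleotides long — form a distinct class
of splicing events whose inclusion depends on specialized machinery, most
prominently the splicing factor SRRM4. In tumor/normal comparisons across
many tissues, a splicing factor that is epigenetically silenced in tumors
should leave three coordinated footprints: lower expression in tumors in
(nearly) every tissue, higher promoter methylation, and reduced inclusion
(PSI, percent spliced in, on the 0–100 scale) of its target exons, with that
reduction coupled sample-by-sample to the factor's expression and to
proliferation. `mexscreen` implements that whole chain of analyses as
data-frame-in, tibble-out functions, together with a seeded synthetic cohort
generator so every stage can be validated against a known ground truth
without any external download.

## The screen

For each feature (splicing-factor expression, or promoter methylation beta
value) and each tissue with at least `min_group_size` tumor and normal
samples (default 20, the same floor the coverage filter uses), `run_screen()`
compares tumor against normal with a two-tailed unpaired
Wilcoxon–Mann–Whitney test and adjusts p-values with Benjamini–Hochberg
within each (tissue, assay) family. The test is implemented in the package:
the exact null distribution of the U statistic is enumerated (by counting
partitions, memoized per group-size pair) whenever the smaller group has at
most 25 observations and there are no ties; otherwise a tie-corrected normal
approximation with a 0.5 continuity correction is used, and each record
states which path produced it. The published analyses name only the test, so
both paths are available and deterministic.

Cross-tissue consistency is summarized by `consistency_scores()`: the number
of tissues significantly up minus the number significantly down, at a
configurable q threshold (default 0.05 — the published figures star
per-tissue significance but never state the counting cutoff, so it is a
recorded knob, not a guess). Features are ranked most-silenced first, ties
broken by the larger mean fold magnitude of the tumor/normal median ratio.
Zero medians never produce infinities: a tissue where both medians are zero,
or only the denominator is, is flagged with an explicit sentinel and excluded
from the mean magnitude, while a feature that is all-zero in both groups
still contributes a p = 1 record so score denominators stay comparable
across features.

## Differential exon inclusion

`differential_psi()` first applies the coverage filter — an exon must have
non-missing PSI in at least 20 tumor and 20 normal samples of a tissue — and
then tests the PSI distributions with the same rank test, BH-adjusted within
the tissue. ΔPSI is the difference of group medians; the published text
says only "absolute PSI difference between the 2 distributions", so medians
were chosen for robustness and consistency with the expression screen, and
the choice is an explicit argument. An exon is called significant when
q < 0.01 *and* |ΔPSI| ≥ 5; the boundary is inclusive (the Methods wording
"≥ 5" wins over the Results wording "> 5"; `strict_dpsi = TRUE` restores the
strict rule). Microexons are classified by 3 ≤ length ≤ 27, inclusive on
both ends. Direction summaries report fractions of decreasing exons for
targets, microexons and non-microexons, with empty denominators reported as
`NA` rather than 0; target enrichment and the excess of decreasing targets
among all significantly changing exons use the package's exact
hypergeometric machinery (one-sided Fisher tests).

## Coupling and the randomization test

The mitotic-index (MI) score of a sample is the mean over signature genes of
the within-cohort z-score of `log2(x + 1)` expression. The signature source
publication does not print a formula, so this construction is the package's
own, documented and swappable: any per-sample profile can be passed wherever
an MI score is accepted. Samples with fewer than half the signature genes
quantified are undefined, and constant genes are dropped since they carry no
ranking information.

`sf_target_coupling()` computes the Spearman correlation
(pairwise-complete, average ranks for ties, at least three pairs) between a
per-sample profile and each target exon's PSI, and takes the median over
targets with a defined correlation. `randomization_test()` compares that
observed median with the same statistic recomputed for `B` background genes
drawn uniformly without replacement from a supplied pool (the focal factor
excluded, no expression matching — none is described in the source
analyses). Three background kinds are first-class labels: random (the
published analysis used 5,000 genes for expression and 500 for methylation),
GO-splicing (425) and microexon regulators (233); the pools themselves are
input data. The one-tailed p uses the add-one rule
`(1 + #{background ≥ observed}) / (B + 1)`, so it is never exactly zero and
is exactly `1/(B+1)` for an observation beyond every background value.
Because the statistic is rank-based, the p-value is invariant to strictly
monotone transforms of every profile, which the test suite asserts.
Correlations are computed within tumor samples of one tissue by default
(pooling across tissues is available but would mix tissue baselines into the
correlation); the published description does not resolve which was used.

Per-exon MI correlations across tumor samples, and the two-sided exact
binomial test (p0 = 0.5) for agreement between the sign of each exon's MI
correlation and the sign of its ΔPSI, complete the proliferation analysis.
The two-sided binomial rule is minimum-likelihood (the sum of the
probabilities of all outcomes no more likely than the observed one),
matching the reference implementation named in the source Methods.

## Perturbation responses

`define_targets()` declares an exon a target when its inclusion gain reaches
the threshold (default ΔPSI ≥ 25, inclusive) in *both* replicates of an
overexpression experiment. `shared_inclusion_sets()` reports exclusive
(UpSet-style) intersection counts across cell lines, whose sizes sum to the
union by construction. Gene-level calls use linear-scale fold changes with a
configurable pseudocount (default 1; the published cRPKM fold changes state
no zero-handling rule) and the per-line cutoff interpretation: a "shared"
gene must pass in every line individually. `cross_dataset_agreement()`
gates features on passing the magnitude cutoff in both datasets — the
Methods tie the cutoffs to both datasets jointly — then tests the same-sign
fraction against a fair coin; an empty intersection is undefined, not p = 1.

## The synthetic cohort generator

`generate_cohorts()` draws, under one seed, the joint structure the analysis
assumes; its defaults are the study conditions the package is validated
under:

* 9 tissues × (40 tumor + 25 normal) samples — comfortably above the
  20-per-group floor while keeping a full cohort generating in well under a
  second;
* 202 splicing factors, one planted as silenced; 600 background genes (the
  randomization pool) and 50 signature genes;
* 800 exons of which 314 are targets, about two-thirds of the targets
  microexons (3–27 nt) and about two-thirds starting at baseline PSI 0, as
  known targets do outside neural tissue;
* a latent proliferation variable π per sample, one standard deviation
  higher in tumors, driving the signature genes (`exp(0.5 π)`) and loading
  negatively (−0.4) on the planted factor's log expression — chosen so the
  recovered MI–factor Spearman correlation is clearly negative at a
  magnitude in the −0.3 to −0.7 range, echoing the reported −0.36 without
  attempting to match it;
* planted-factor expression divided by 3.67 in tumors (the reported mean
  fold change) on low tissue baselines (uniform 2–10 expression units);
  promoter methylation shifted by +0.8 on the logit scale in tumors and
  coupled positively to π so methylation anticorrelates with expression
  within tumors;
* target PSI = `clamp(baseline + 8·log1p(factor expression) + N(0, 8), 0,
  100)` — the link is monotone rather than linear because every downstream
  statistic is rank-based, so only monotonicity matters for power; the slope
  and noise give per-target correlations around 0.3 and tumor ΔPSI of a few
  PSI units to tens of units, the regime the thresholds were designed for;
* 5% of PSI cells masked missing; non-target exons independent of the
  factor with uniform baselines.

Setting every effect to zero (`null_config()`) makes tumor and normal
exchangeable, which is the basis of the calibration experiments. What the
generator does *not* emulate — empirical TCGA expression distributions,
batch structure, tumor purity confounding, correlated exons within genes —
bounds what green tests mean: they demonstrate the statistics are computed
correctly and are calibrated and powered under the assumed structure, not
that the biological conclusions transfer to any particular real cohort.

## Validation experiments and problem sizes

The acceptance suite runs, at sizes chosen to keep the whole suite in a few
minutes on one core:

* exact-test oracles — full enumeration of rank-test labelings for group
  sizes up to 7 (510 random inputs), 1,000 random contingency tables for the
  Fisher/ORA identity, 1,000 random p-vectors against an independent
  sort-based BH oracle;
* null calibration — 100 null cohorts (2 tissues × 25+25 samples, 250
  exons) for the significant-call rate, and 200 null datasets (1 tissue, 30
  tumors, 40 targets, B = 199) for approximate uniformity of the
  randomization p (Kolmogorov–Smirnov distance < 0.1);
* planted recovery — 50 cohorts at full default scale (202 factors, 9
  tissues, B = 500), requiring the planted factor to rank first in both
  assays in ≥ 95% of runs, randomization p < 0.05 in ≥ 80%, a pooled
  fraction of decreasing significant target exons above 0.7, and a negative
  MI–factor correlation in ≥ 95%;
* threshold semantics, closed-form lab calculations
  (`2^-ΔΔCt`, `length × width² / 2`), and byte-level determinism of the
  generator.

`scripts/acceptance.R` recomputes the pipeline's headline quantities from a
fresh default cohort under a caller-supplied seed.

## Numerical choices and limitations

Ranks use average ties throughout. Spearman correlations with fewer than
three complete pairs, or a constant member, are `NA`, never 0. The exact
binomial pmf is computed by direct products for n ≤ 64 (exact to the last
bit for dyadic p0) and in log space above. BH families are always declared
by the caller; the package never adjusts across tissues. Exon coordinates
are opaque strings; no strand or coordinate arithmetic is performed
anywhere, because no statistic here consumes them. The vast-tools reader's
quality cutoff is an explicit argument (default `"VLOW"`, dropping only
grade-`N` cells) because the published pipeline removes "very low quality"
quantifications without naming the grade. Survival analysis, GO-hierarchy
traversal and PSI quantification from raw reads are out of scope; inclusion
tables and TSV matrices are the entry point.
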