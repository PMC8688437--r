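---
title: "Methods: 5'-anchored miRNA quantification and downstream statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 5'-anchored miRNA quantification and downstream statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirwin)
```

## Overview

`mirwin` implements the computational core of a small-RNA knockdown study
design: quantify mature miRNA abundance from small-RNA sequencing reads in an
isomiR-aware way, test miRNAs and genes for differential expression between a
knockdown and a control condition under a negative-binomial model, and ask
whether a differentially expressed miRNA leaves a regulatory footprint — a
shift in the cumulative distribution of its target genes' fold changes
relative to non-target background genes. Cross-cell-line overlap and
concordance statistics, and a set of clinical/bench statistics (ROC/AUC,
median-split survival, 2^-ddCt, ChIP percent-input, xenograft volume), round
out the workflow. Everything runs on synthetic data produced by the package's
own generators, so the full pipeline is testable on a laptop with no
downloads.

## 5'-anchored window quantification

Mature miRNAs are not sequenced as a single sequence: real libraries contain
isomiRs, variants whose 5' and/or 3' ends differ from the annotated mature
coordinates. Because the 5' end defines the seed region, quantification here
anchors on it:

1. Reads are adapter-trimmed, collapsed to distinct sequences with counts,
   filtered to 18–28 nt inclusive, and mapped to the genome allowing zero
   mismatches. Sequences without a perfect match are discarded.
2. For each annotated mature miRNA, all distinct sequences with an alignment
   on the miRNA's chromosome and strand whose 5' position lies within ±3 nt
   of the annotated mature 5' end form that miRNA's *window set*.
3. The window sequence with the maximal count is the *reference sequence*.
4. The miRNA's abundance is the summed count of window sequences whose 5'
   position equals the reference's observed 5' position — which may differ
   from the annotated one if the dominant isomiR is offset.

Assumptions and conventions worth making explicit:

* **Offset orientation.** Offsets are reported in mature-RNA orientation
  (negative = upstream of the annotated 5' end), so plus- and minus-strand
  loci behave identically; a mirrored construction on the two strands gives
  identical results, and the tests assert this.
* **Reference ties** break by smaller |offset| to the annotated end, then
  longer sequence, then lexicographic order. Any fixed rule would do; this
  one favours the annotation and makes output deterministic.
* **Multi-mapping sequences** contribute their full count to every miRNA
  whose window captures one of their alignments. No fractional apportioning
  is attempted; for paralogous families this double-counts, and the window
  detail table makes it visible. A sequence with several alignments inside
  one window still counts once for that miRNA, keyed at the alignment
  closest to the annotated end.
* **Adapter trimming** looks for the leftmost exact match of the adapter's
  first 8 nt anywhere in the read, then falls back to progressively shorter
  prefixes (down to 5 nt) anchored at the read's 3' terminus. Reads with no
  identifiable adapter are rejected and counted. This is a deliberate,
  simple stand-in for production trimmers: with exact adapter sequence and
  modest error rates it identifies essentially all adapters, and it is fully
  specified, which matters more here than tolerance to adapter errors.
* The internal exact matcher serves toy genomes; externally mapped data can
  enter through SAM ingestion, where any record with a non-full-length CIGAR
  or a nonzero `NM` (or non-trivial `MD`) is discarded to preserve the
  perfect-match contract.

## Differential expression

The DE stage reimplements the classic count-based exact-test workflow from
its underlying algorithms:

* **TMM normalization.** The reference library is the one whose
  75th-percentile count proportion is closest to the mean of those
  percentiles. Per-feature M and A values against the reference are doubly
  trimmed — default 30% total on M (15% per tail) and 5% on A — and the
  scaling factor is 2 to the precision-weighted mean of the surviving M
  values, rescaled so factors have geometric mean 1. The precision weights
  are binomial delta-method variances evaluated on counts-per-million rather
  than raw library scales; this makes the factors exactly invariant to a
  uniform rescaling of any single library (a property the tests assert at
  1e-6) at the cost of a sub-0.2% numerical difference from edgeR's weights
  when library sizes are very unequal.
* **Common dispersion.** A pooled method-of-moments estimate: counts are
  scaled to a common effective library size, each feature contributes
  `max(0, (s² − m)/m²)` from its pooled within-group variance, and the
  common value is the median over features with normalized mean above 5.
  This is deliberately *not* a conditional-maximum-likelihood estimator: it
  is transparent, and adequate at desk scale. The median across noisy
  per-feature moment estimates is biased low by roughly 15–20% at 3 vs 3
  replicates (the tests document recovery of a 0.2 truth within
  [0.15, 0.25]); where calibration at a known dispersion matters, pass the
  dispersion explicitly.
* **Exact test.** Counts are scaled to the geometric mean of effective
  library sizes and rounded half-up to pseudo-counts. Each group's sum is
  modelled as negative binomial with mean proportional to its replicate
  number and dispersion φ/replicates; because both groups then share the
  same NB probability parameter, the distribution of one group's sum
  conditional on the total is free of the unknown mean. The two-sided
  p-value sums all conditional outcomes no more probable than the observed
  one (minimum-likelihood rule, with a 1e-8 relative tolerance for
  floating-point ties). At φ = 0 this reduces exactly to the conditional
  binomial test, which the tests assert to 1e-9. Fold changes are
  `log2((mean₂ + 0.5)/(mean₁ + 0.5))` on normalized counts; the 0.5 prior
  keeps zero-count features finite.
* **Calling.** BH step-up FDR (via `p.adjust`) with a strict `<` threshold;
  up/down is the sign of the fold change among FDR-passing features.

One caveat surfaced by testing: exact conditional tests have discrete,
conservative null distributions, so null p-values are stochastically *larger*
than uniform. The test suite therefore checks uniformity in the
anticonservative direction (the empirical CDF never exceeds the uniform CDF
by more than noise) plus the type-I error rate, rather than a two-sided
uniformity test that any exact test would fail.

## The target CDF-shift test

If a miRNA falls after knockdown, repression of its targets is released, and
their fold-change distribution should shift up relative to genes it does not
target. For one miRNA, the target sample is the fold changes of its expressed
target genes, the background is all remaining expressed genes (cognate
targets excluded, so the two samples partition the expressed set), and the
comparison is a two-sample Kolmogorov–Smirnov test with the asymptotic
Kolmogorov p-value evaluated at `sqrt(mn/(m+n))·D` (series truncated at 100
terms or 1e-12, appropriate because both samples number in the hundreds to
thousands here). A signed shift — median target LFC minus median background
LFC — is reported alongside, and the result is *direction-consistent* when
its sign opposes the miRNA's own fold change. Fewer than 10 expressed targets
flags the result underpowered without suppressing it. Ties in fold changes
are handled by the ordinary empirical-CDF step construction; no jitter is
added, keeping results deterministic.

Overlap of DE sets across cell lines is tested with the one-sided
hypergeometric tail (identical to one-sided Fisher), with the universe
defined as the miRNAs detected in both cell lines — the original analysis
does not state its universe, so it is an explicit argument here, never a
hidden default. Concordance of shared miRNAs' fold changes uses the Pearson
correlation with a t-distribution p-value on n − 2 degrees of freedom.

## Clinical and bench statistics

* **ROC/AUC** is the Mann–Whitney probability with half credit for ties,
  with a DeLong placement-variance 95% interval clipped to [0, 1] (the
  original report does not state its CI method; DeLong is deterministic,
  which bootstrap is not).
* **Median-split survival**: ties at the median go to the low-expression
  group (a fixed, documented policy); product-limit curves, log-rank
  chi-squared on 1 df, and a hazard ratio from the log-rank
  observed/expected decomposition `(O_high/E_high)/(O_low/E_low)` — chosen
  over a Cox fit because no covariates are in scope.
* **2^-ddCt** uses replicate means with standard errors of the four Ct means
  propagated in quadrature into a fold-change interval.
* **ChIP percent-input** adjusts the input Ct by `log2(1/fraction)` before
  comparison; **tumor volume** is `length × width²/2`.

## What the synthetic data emulates — and what it does not

The generators define the study conditions under which everything above is
tested:

* **Toy genomes** are uniform-random A/C/G/T, 40–100 kb by default: long
  enough that an 18–28 nt sequence is unique with overwhelming probability,
  so planted loci map uniquely (the planter verifies uniqueness explicitly
  and keeps a 10 nt margin between loci so isomiR windows cannot collide).
* **isomiR structure**: 5' offsets are drawn from a distribution
  concentrated at the annotated end — P(0) = 0.80, P(±1) = 0.08,
  P(±2) = 0.015, P(±3) = 0.005 — exercising every window slot while keeping
  the annotated end modal, as in real libraries; 3' variation is uniform on
  ±2 nt and extends with genomic template sequence, which specifically
  exercises the rule that abundance aggregation keys on 5' ends only. The
  source analysis documents only the ±3 window, not its library's isomiR
  composition, so these are stated stand-ins, not estimates.
* **Counts** are negative binomial with dispersion 0.1, 3 vs 3 replicates,
  10% of genes at |LFC| = 1, base means log-uniform on [20, 500] — a typical
  bulk RNA-seq knockdown regime. Target genes of planted miRNAs carry an
  additional repression-release shift δ (default 0.6 log2 units, sign
  opposite the miRNA's own fold change).
* **Clinical tables** use a binormal score model (population AUC =
  `pnorm(mu/sqrt(2))` fixes the case mean) and exponential survival with the
  hazard multiplied by the target ratio above the median expression,
  censored administratively at 60 months.
* **Reproducibility**: one global seed cascades to per-component seeds by
  fixed offsets, and every generator is bit-reproducible given its seed.

What passing tests on these data do *not* show: robustness to adapter
sequencing errors or non-templated 3' additions (reads here are templated up
to substitution errors), to mapping ambiguity in repetitive genomes (toy
genomes are random), to tagwise dispersion heterogeneity (one common φ), or
to non-proportional hazards and covariate confounding in survival. Those are
properties of real libraries and cohorts that these generators deliberately
do not imitate.

## Problem sizes and numerical choices

The test suite and the acceptance script run, by design, at these sizes: 200
random quantification instances (up to 50 loci and 5,000 distinct sequences)
against a brute-force all-pairs oracle; end-to-end read recovery on a 100 kb
genome with 25 loci and ~25,000 reads; exact-test calibration and power on
10,000-feature matrices at 3 vs 3; shift-test power over 100 planted
replicates and 1,000 null replicates; 1,000 exchangeable survival replicates
for log-rank calibration; and a two-cell-line demo pipeline small enough to
finish in well under five minutes on one CPU. Seeds fix every run;
re-running the demo pipeline with the same seed reproduces byte-identical
stage outputs, which the manifest's checksums make easy to verify.

## Known limitations

* The trimming rule is exact-match only; adapters with sequencing errors in
  their first five nucleotides escape it (such reads are rejected, not
  mis-trimmed).
* Counts from paralogous miRNAs sharing window sequences are double-counted
  by design and must be interpreted with the window detail in hand.
* The common-dispersion estimator is biased low at very small replicate
  numbers (see above); the exact test inherits mild anticonservatism if that
  estimate is used uncritically at n = 3 vs 3.
* The hypergeometric overlap test conditions on a user-supplied universe;
  conclusions move with it.
* No GLM framework: multi-factor designs, covariates and trended dispersion
  are out of scope.
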