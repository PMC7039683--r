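---
title: "enhancerscan: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{enhancerscan: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`enhancerscan` reconstructs, as reusable and tested components, a pipeline
for finding tissue-specific enhancers from sorted-cell ATAC-seq and for
prioritizing noncoding risk variants that may disrupt them. This vignette
is the package's own account of its models: the assumptions behind each
stage, the parameters that matter, the numerical conventions, and what a
green test on synthetic data does and does not establish.

## Coordinates and sequence conventions

All intervals are 0-based, half-open (the BED convention), everywhere
inside the package; 1-based inputs (SNP tables) are converted once at the
reader boundary. A genome is a named character vector in which lowercase
bases are the repeat representation (UCSC-style soft masking); the repeat
fraction of a window is simply its lowercase fraction, and GC fraction
excludes `N` from the denominator. These conventions are deliberately
boring: a single coordinate system and a single mask representation remove
the most common source of silent off-by-one errors in this kind of
pipeline.

## Differential accessibility

Nucleosome-free fragments are those strictly shorter than 100 bp.
Fragments yield two Tn5 cut sites each (left end +4, right end −5, the
standard transposase-offset correction). The internal peak caller —
a deliberate, simplified stand-in for MACS2, which is out of scope —
smooths per-base cut density with a centered running mean (150 bp),
estimates local background over a 10 kb span floored at the genome-wide
mean, and reports maximal runs at ≥ 4-fold enrichment, merging runs closer
than the smoothing window. It is deterministic and has no model of
duplication or mappability; it is adequate for clean synthetic data and
for peak BEDs the user supplies instead.

Counting assigns a fragment to a region when its midpoint falls inside
(unambiguous single assignment); library sizes are genome-wide per-sample
totals. The per-region test is a two-sided conditional binomial: pooled
group-A counts against the expected split from group library sizes. With
two replicates per group at synthetic scale, a negative-binomial
dispersion model (the DiffBind/edgeR route on real data) is
unidentifiable; the conditional binomial has the correct null behavior
(the package asserts ≤ 2% calls at FDR 0.01 on a balanced Poisson null)
at the cost of treating replicates as exchangeable pools. Fold changes
are computed on library-size-normalized means with a pseudocount of 1
(the source method is silent here; the pseudocount keeps log2 finite),
and calls require both |log2 FC| > 0.5 and BH-adjusted q < 0.01. The
linear-scale "fold change > 2" variant that sometimes appears alongside
the log-scale threshold is inconsistent with it; the log-scale form is
the default and the thresholds are plain config values.

## Active-enhancer annotation

H3K27Ac support means overlapping a peak or an inter-peak "flanked"
region no longer than 1500 bp; with several peak tracks (e.g. two
developmental stages) the default is a union ("and/or" support), with
intersection available. Elements overlapping a transcription start site
are removed; since "overlapping a TSS" has no defined width for point
TSSs, they are padded ±500 bp (configurable). Each surviving region is
resized to the 400 bp window whose center stays inside the region and
which maximizes summed cut density, ties going leftmost; windows are
clipped at chromosome ends with a warning. Elements more than 70% repeat
(strictly greater) are dropped. Gene assignment takes up to the two
nearest TSSs within 100 kb of the element midpoint, distance ties broken
lexicographically — the midpoint anchor makes the rule deterministic.

## The gapped k-mer SVM

The kernel counts gapped k-mers (k = 6 informative columns of an l = 10
word) shared between all word pairs of two sequences. Two exact routes
coexist:

* **pairwise**: `K(A,B) = Σ f(m(u,v))` with `f(m) = C(l−m, k)` for
  `m ≤ l−k`, computed by 2-bit packing, XOR and popcount;
* **feature map**: for each of the `C(10,6) = 210` position subsets,
  count the `4^6` gapped words per sequence and accumulate the Gram
  matrix by one BLAS rank-k update per subset.

The float (`ssyrk`) route is exact because every intermediate value is an
integer below 2^24; the tests assert bit-equality between the two routes
and against an independent R-level feature-map oracle. Reverse-complement
collapsing augments each sequence's word multiset with reverse
complements, which makes every score strand-invariant and automatically
gives `w(u) = w(rc(u))`; canonical (lexicographic-minimum) 10-mers key
the serialized weight table.

The soft-margin dual is solved exactly on the normalized Gram matrix by
an SMO solver (maximal-violating-pair working set, C = 1, tolerance
1e-3); no hyperparameter search is performed because none is specified.
The weight of a word is its unnormalized decision contribution,
`w(u) = Σ_sv (αy)_sv K(u, sv)/√K(sv, sv)`, bias excluded — so deltaSVM
differences are bias-free and a sequence score is exactly the sum of its
word weights. Cross-validation is stratified; auROC is trapezoidal (and
checked against the rank-statistic identity), auPRC is step-interpolated
average precision.

Negative sets draw, per positive, `ratio = 10` random genomic windows
matching GC within 0.05 and repeat fraction within 0.10, excluding the
positive loci and previously drawn windows; failure after a bounded
number of tries reports the unmatched sequence rather than silently
relaxing tolerances.

## deltaSVM and the resampling null

A SNP's deltaSVM is the alt-minus-ref difference of window scores over
the 19 bp window centred on it; with l = 10 exactly the ten words
covering the SNP contribute, and the tests assert that decomposition
exactly. The null is 1000 SNPs within 100 kb of the locus, drawn once
per locus from the supplied catalog (without replacement, tested SNPs
excluded) or uniformly with random alternate bases when no catalog
exists. The test is lower-tailed by default — the hypothesis is enhancer
disruption — with ties counting toward the null (conservative), empirical
p = count/1000 with no smoothing (matching the published arithmetic
2/1000 × 14 = 0.028), and Bonferroni correction by the number of tested
SNPs.

## Motif analytics

PWMs are probability matrices regularized with a pseudocount (0.01);
scores are natural-log odds against the background, and the relative
score is min–max normalized, scanned on both strands at the standard 80%
threshold. The allele-specific site-loss rule requires a detected site
(relative ≥ 0.8) with raw log-odds ≥ 5.0 under one allele and < 2.0 — or
no detection — under the other; the raw-score scale of those published
thresholds is not stated at source, so natural-log odds with uniform
background is the convention here and both thresholds are configurable.
Footprints aggregate shifted cut counts over hits, orientation-normalized,
across offsets −100..width+100; the evidence statistic is the core/flank
mean ratio (no posterior occupancy model — that is out of scope). The
regulatory network draws a directed edge from TF a to TF b whenever an
element assigned to b's gene carries a's motif, weighted by element count.

## Homology testing

The deep-homology test asks whether a test sequence aligns to reference
sequences better than composition-matched controls: its reverse
complement, its non-biological reversal, and three Fisher–Yates shuffles.
The aligner is affine-gap Needleman–Wunsch (match +1, mismatch −1, gap
open −5, extend −1 by default; a gap of length g costs open + (g−1)·
extend) with deterministic tie-breaking (diagonal, then gap in the second
sequence, then in the first). The published analysis used CLUSTALW, whose
exact scoring is not reproduced; consequently the printed dash and block
counts of the original are parameter-dependent and only the z-score logic
is asserted. Three-way alignments are progressive: the closest pair
(highest pairwise identity) aligns first, and the third sequence aligns
against the two-row profile with average-column scoring, dashes counted
over all rows and over the query row separately (both are reported
because the original's convention is ambiguous). Percent identity is
defined over the longer input sequence, making it symmetric up to the
one-match ambiguity that equal-score optima permit; identity blocks are
maximal runs of ≥ 5 identical gap-free columns (an exact-length-5 option
exists). A test z-score beyond ±2 against the five controls is the
working significance convention, mirroring the "almost one s.d. fewer
insertions" style of evidence in the source analysis.

## The synthetic world

`make_dataset()` generates, from one seeded RNG stream with documented
draw order: an i.i.d. background genome at 41% GC with ~10% lowercased
tandem stretches; non-overlapping 400 bp enhancers on a slot grid (60
population-A, 40 population-B, 60 shared by default) with three planted
motif instances per A-enhancer; sub-100 bp fragments at 30 per region per
replicate with a 4-fold bias for population-specific regions, plus ~200 ±
20 bp nucleosomal fragments and genome-wide background noise; H3K27Ac
peaks overlapping or symmetrically flanking 80% of A/shared enhancers
(per-side gaps drawn so the inter-peak gap never exceeds 1500 bp —
the literal "per-side up to 1500 bp" reading would contradict the
requirement that every supported enhancer classifies as K27-high); TSSs
kept clear of enhancers; a 3000-SNP catalog within 100 kb of one planted
motif-disrupting SNP (consensus base → worst base at the motif's
strongest column); and two "reference species" homologs of the planted
SNP's enhancer at 25% divergence. Fragment cuts landing inside planted
motif instances are suppressed to 20% — that is what makes footprints.

Two generator choices deserve explanation. First, default PWM columns
alternate 0.95/0.85 consensus probability rather than being uniform: for
a uniform width-10 PWM every two-mismatch word scores *exactly* at the
80% relative threshold (each mismatch costs exactly 10% of the score
range), so rescan rates would hinge on floating-point rounding.
Heterogeneous columns break that degeneracy and better resemble real
motifs. Second, population-specific enhancer counts and depths are set so
that pooled counts are ~60 vs ~15 for specific regions — deep enough that
the binomial test has essentially full power, which is what the stated
4-fold/FDR-0.01 world implies.

What a green synthetic run establishes: the plumbing is correct, the
statistics have their stated null behavior, planted signal of the stated
effect size is recovered, and everything is reproducible bit-for-bit
under a seed. What it does not establish: performance on real data —
there is no read-level error, no duplication, no mappability structure,
no LD between SNPs, no diploidy, and i.i.d. background sequence is far
more learnable than real genomic background. Published real-data figures
(cross-validation auROC 0.88, genome-scale element counts) are context,
not targets, and are not asserted anywhere.

## Reproducibility

Every stochastic entry point takes an explicit seed and restores the
caller's RNG state. `run_all()` writes a provenance record (config hash,
seed, package and R versions) and an md5 manifest of every output; the
acceptance tests rerun the default pipeline twice and require identical
manifests. The full default pipeline completes in well under two minutes
on one CPU.

## Known limitations

* The peak caller is intentionally minimal; use external peak BEDs for
  real data.
* The conditional binomial ignores replicate overdispersion; with ≥ 3
  replicates per group on real data an NB model would be preferable.
* The SMO solver stores the full Gram matrix (fine to ~5000 sequences;
  beyond that the reference tools' trie kernels are the right tool).
* CLUSTALW scoring, GREAT's ontology statistics, de novo motif discovery
  and occupancy-model footprinting are explicitly out of scope.
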