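---
title: "Methods: super-enhancer landscape analysis in selandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: super-enhancer landscape analysis in selandscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selandscape)
```

## The problem

Super-enhancers (SEs) are large clusters of enhancer elements carrying
exceptionally dense H3K27ac signal; they tend to sit near cell-identity and
oncogenic driver genes. In a matched tumor/normal cohort design, each
patient's tumor is profiled alongside adjacent normal tissue, so SE gains
and losses can be assessed within patients and their recurrence counted
across the cohort. `selandscape` implements that analysis end-to-end: SE
calling per sample, a cross-sample consensus catalog, promoter-normalized
differential statistics, recurrence and discovery-saturation summaries,
candidate prioritization, and target-gene assignment by signal–expression
regression. A deterministic synthetic-cohort generator with a planted truth
set makes the whole pipeline testable offline.

## Per-sample SE calling

The calling procedure follows the ROSE (Rank Ordering of Super-Enhancers)
logic:

1. **Promoter exclusion.** Any enhancer peak overlapping a window of
   ±`tss_window` (default 2500 bp, the ROSE default) around an annotated
   TSS is removed whole — never trimmed. The window is configurable
   because annotations differ in TSS precision.
2. **Stitching.** Remaining peaks on a chromosome are single-linkage
   chained whenever the gap between them is ≤ `stitch_gap` (default
   12,500 bp). The boundary is inclusive: "within 12.5 kb" stitches a gap
   of exactly 12,500 bp. Book-ended intervals (gap 0) always merge.
3. **Quantification.** Each stitched region's signal density is an
   RPKM-like quantity: summed per-base coverage divided by region length
   in kb, divided by total track signal in millions; an optional matched
   input control is subtracted on the same scale, floored at 0 so
   densities remain rankable.
4. **Cutoff.** Densities are sorted ascending and both axes scaled to
   [0, 1]; the cutoff is the density at the index maximizing
   $x_i - \hat y_i$, the point of maximum vertical distance below the
   diagonal. For a convex rank curve this is exactly the point where the
   tangent slope equals 1 — ROSE's published geometric criterion —
   without reproducing ROSE's numerical code. Ties take the smallest
   index, which calls more SEs and is therefore conservative for
   discovery. Regions strictly above the cutoff are SEs.

Degenerate inputs are rejected explicitly: fewer than 3 regions or
all-equal densities cannot define an inflection. Because both axes are
scaled, the SE/TE partition is invariant to multiplying all signal by any
positive constant — a useful sanity property, and the reason whole-track
scale factors cancel (see below).

## Consensus catalog and promoter normalization

Consensus loci are the single-linkage merge (≥ 1 bp overlap) of all
samples' SE intervals, pooled jointly across groups; per-group merging
first would make the catalog depend on group labels, and a joint merge is
the simplest order-invariant choice. A sample is a *member* of a locus iff
one of its own SE calls overlaps it — i.e. the locus met SE criteria in
that sample — and recurrence `k of n` counts members within a group.

The loci × samples signal matrix holds RPKM-like densities. Because
RPKM divides by total track signal, samples with different off-target
(non-enhancer) signal fractions — varying ChIP efficiency — are not
directly comparable. Promoter normalization corrects this under the
assumption that aggregate promoter activity is approximately constant
across samples: each sample's mean density over all TSS ± 1 kb windows is
computed, and its column is multiplied by
`median(promoter means) / own promoter mean`. The cohort median is used as
the reference because it is robust to outlier samples. The transform is a
per-column positive scalar, so within-sample rank order of loci is
preserved.

## Differential statistics, recurrence, saturation, candidates

Differential SE analysis between two groups uses a pooled-variance
two-sample two-sided Student's t-test per locus on normalized densities.
The unpaired test is the default despite the matched design, for fidelity
to the stated analysis method; a paired variant sits behind a flag. Fold
change is `log2((mean_a + eps)/(mean_b + eps))` with pseudocount
`eps = 0.1` density units guarding against empty loci; a per-pair variant
(mean of per-pair log2 ratios) is available behind a flag since "mean
log2 fold change" is ambiguous between the two. Selection uses raw P
(default `p < 0.01` with `|log2FC| > 1`); Benjamini–Hochberg q-values are
computed and reported but never used to select, mirroring the analysis
this package operationalizes.

The saturation curve adds a group's samples in acquisition order and
counts distinct consensus loci discovered; the saturation index is the
smallest prefix reaching a target fraction (default 95%) of the final
count. The final count is order-invariant by construction.

Candidates are the intersection of the top `top_n` (default 100) loci
ranked by descending fold change (ties by ascending P, then locus id) with
loci recurrent in at least `min_k` (default 9) group samples.

## Target assignment

For each consensus locus, every gene with a TSS within 500 kb of the locus
center (inclusive at exactly 500,000 bp, strand ignored) and mean
expression > 2 TPM across the used samples is regressed: expression on
normalized SE density, ordinary least squares across the samples having
both assays. The correlation test (`t = r√(n−2)/√(1−r²)`, df = n−2,
two-sided) gives the P value; genes with `p < 0.05` are significant and
the smallest P (ties: larger |r|, then gene id) is the assigned target. No
multiple-testing correction is applied at assignment — raw P < 0.05 is the
stated rule — but q-values are reported alongside. Whether to pool groups
in the regression is left configurable; the default uses all samples with
both assays, which maximizes signal variance and n.

## The synthetic cohort: what it emulates, and what it does not

`cohort_config()` defaults are the stated world of the matched design: 15
tumor/normal pairs on one 10 Mb chromosome, 50 planted SE loci — 20
tumor-gained (recurrence 12 of 15 tumors, log2 effect 2), 20 shared, 10
normal-only — 200 genes (one true target per planted locus plus decoys
inside every regression window), 120 background peaks per sample, and
expression for each true target linear in its locus's true signal at
design correlation ρ = 0.8 with Gaussian noise truncated at 0. Defaults
not fixed by the design were chosen once as field-realistic: per-peak
log-normal jitter with sdlog 0.15 (typical biological+technical spread of
peak heights), baseline coverage 2× with planted loci at
`2^effect`-fold, and 3–8 constituent peaks per planted locus covering
~70% of a 30 kb span.

Every sample carries the same constituent-peak *footprint* at each planted
locus; carriers get `baseline × 2^effect` coverage there, non-carriers
baseline. This keeps the consensus-locus fold change interpretable: the
coverage fraction cancels, so a full-recurrence locus has expected log2FC
equal to the configured effect. At partial recurrence `k` of `n`, the
group-mean fold change is `log2((k·2^e + (n−k))/n)` — ≈ 1.77 for
`e = 2, k = 12, n = 15` — because group means, not carrier means, are
compared. Tests assert the k-adjusted expectation.

Two kinds of sample-level scale variation are planted. Whole-track scale
factors (log-uniform in [0.5, 2]) exercise the I/O and bookkeeping but are
mathematically invisible to RPKM quantification. What actually distorts
cross-sample comparability — and gives promoter normalization real work —
is each sample's off-target signal mass, emitted on a decoy contig and
drawn log-uniform in [0.5, 2] relative to 1 Mb of baseline coverage. This
emulates varying ChIP efficiency (fraction of reads in peaks), the effect
promoter normalization exists to correct.

The generator does **not** emulate: read-level noise (everything is
coverage-valued), irregular peak shapes, copy-number variation, blacklist
artifacts, inter-patient heterogeneity of promoter activity, or expression
measurement models beyond additive Gaussian noise. A green recovery test
therefore establishes that the pipeline's logic recovers a planted
landscape under clean, favorable-geometry conditions — not that it is
robust to every artifact of real ChIP-seq.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open throughout; 1-based conversion happens
  only at the GenomicRanges boundary, and chromosome ordering is
  normalized so interval operations are independent of input order.
- bedGraph queries are exact sums of value × overlap via per-chromosome
  cumulative masses; queries on chromosomes absent from a track return 0
  with a warning rather than an error, tolerating assembly-subset
  fixtures.
- Zero variance in both t-test groups with equal means yields `p = 1`
  (never NaN); unequal means with zero variance yield `t = ±Inf` and P at
  the double floor. Perfect correlations likewise report P at the floor,
  never 0 underflowing to nonsense downstream.
- Zero-variance rows in the z-score transform become all-zero with a
  warning rather than erroring a whole heatmap.
- `find_cutoff` tie-breaks to the smallest index; a strictly linear ramp
  (all ties) therefore returns the minimum density, labelling all but the
  minimum-density regions super — the conservative extreme.

## Known limitations

- Consensus merging can chain overlapping SE calls from different samples
  into loci larger than any single call ("daisy-chaining"); with ≥ 1 bp
  single-linkage this is inherent, and the membership matrix preserves the
  per-sample picture.
- SE calling precision on the synthetic cohort is deliberately not a pass
  criterion: the rank-curve cutoff sits at the top of the background band,
  so a handful of background regions cross it per sample, as in real data
  where catalog size exceeds any planted truth.
- The paired t-test and per-pair fold-change variants are provided but not
  defaults; switching them changes selection and should be reported with
  results.
- Hi-C/Hi-ChIP loop support, GSEA, motif analysis and deconvolution are
  out of scope by design; assignments are regression-based only.
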