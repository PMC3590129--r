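---
title: "Methods: a desk-scale whole-blood miR-ome pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale whole-blood miR-ome pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirkd)
```

`mirkd` re-implements, at desk scale, the analysis stack used to profile the
whole-blood small RNA transcriptome of children with Kawasaki disease across
the acute and convalescent phases: read preprocessing, hierarchical
zero-mismatch miR annotation with isomiR summaries, negative-binomial
differential expression, pathway enrichment of predicted targets, and the
clinical validation statistics. This vignette documents the models, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The synthetic study and what it emulates

Clinical small RNA libraries of this design carry 5–23 million reads across
12 matched acute/convalescent pairs. Those data are neither retrievable nor
brute-forceable on a desk, so the generator produces a scaled study whose
*structure* matches the real one while every quantity stays checkable by
exhaustive oracles:

- **Reference.** A 50 kb genome on two synthetic chromosomes holds 50 miR
  precursors (each with a 21–23 nt mature arm, modal 22 nt, and a star arm
  on 30% of loci) and 15 non-coding RNA records (lincRNA, rRNA, snRNA,
  snoRNA, tRNA) verbatim at recorded coordinates, separated by random
  flanks. 50 kb is large enough that 17–27 nt reads map essentially
  uniquely, and small enough that a naive all-substring scan remains a
  feasible test oracle. Precursor margins of at least 3 nt around each arm
  guarantee that every representable isomiR offset stays inside the
  precursor.
- **Counts.** Per-arm, per-library counts are negative-binomial with
  variance `mean + alpha * mean^2` (default `alpha = 0.1`, a typical
  biological-replicate dispersion for bulk count data), library scaling
  factors log-normal around 1 (sd 0.15), baseline abundances log-normal
  across loci, and star arms at 5–15% of their mature arm. By default 10%
  of loci carry a planted acute-phase log2 fold change of +2 — all planted
  effects point upward, matching the observed pattern that differentially
  expressed miRs in this disease are acutely elevated.
- **Reads.** Each counted read is its arm's sequence modified by an isomiR
  offset, plus a ligated 21-nt 3' adapter, padded to the 36-cycle instrument
  read length. The offset distribution weights 3' variation fourfold over 5'
  variation (non-zero probability 0.4 vs 0.1), reflecting the 3'-dominant
  isomiR variation these libraries show — the documented situation where a
  dominant read is one base shorter at the 3' end than its annotation.
  Because the adapter is proprietary in the real protocol, a fixed synthetic
  21-mer is used; both it and the read length are configurable.
- **Noise.** Per library: 10% ncRNA fragments, 3% random unmappable junk,
  12% inserts outside the 17–27 nt window (split between 10–16 nt and
  28–33 nt; long inserts that leave the adapter under 6 bases of overlap
  become no-adapter reads), and 1% of otherwise-qualified reads carry one
  sub-Q10 base. These rates were chosen so the filter tallies land where
  such libraries report them: ~86% of reads qualified and ~75% of all reads
  miR-derived. Qualities are a discretized normal (mean 35, sd 4, clamped to
  [2, 40]).
- **Sidecars.** Every read records its true class, source, offsets and the
  filter category it was constructed to land in, so preprocessing and
  annotation can be scored read by read.

What the generator does *not* emulate: sequencing error (substitutions,
indels), RNA secondary structure, cross-mapping between paralogous miR
families, adapter dimers, and the scale of real libraries. Passing tests
therefore demonstrate correctness of the algorithms under the stated count
model, not robustness to real-instrument artifacts.

Determinism: all three stages draw from seeds derived from `config$seed`
(offsets 0, 1, 2), so regeneration is byte-identical, including the FASTA,
GFF3 and FASTQ writers (the GFF3 run-date header is stripped for this
reason).

## Preprocessing

Adapter trimming scans for the leftmost read position where the adapter
prefix aligns to the read suffix with at most 2 mismatches over a full
21-base overlap; terminal overlaps of at least 6 bases are allowed with the
budget scaled as `floor(2 * overlap / 21)`. The 2-mismatch budget is applied
at the adapter-alignment step because it is the only alignment in the
pipeline where mismatches can occur — all reference mapping is exact. The
length window is inclusive, `17 <= length <= 27`. The quality rule defaults
to the strictest defensible reading — minimum per-base Phred of 10 over the
trimmed insert — with a `quality_mode = "mean"` alternative, since a
mean-based reading of the rule is also plausible. Filter categories are
assigned with fixed precedence `no_adapter > too_short > too_long >
low_quality`, so each read is counted exactly once and the categories always
sum to the total.

## Annotation

Collapsed reads are classified against the reference in a fixed hierarchy:
no exact genome hit ⇒ `unmapped`; exact hit in the ncRNA set ⇒ `ncrna`
(ncRNA exclusion precedes any miR call, so e.g. a tRNA fragment that also
sits in the genome never counts as a miR); a genome hit contained in a
precursor on the annotated strand, covering the arm's seed (positions 2–8)
with both end offsets within ±3 nt ⇒ `known_mir` with offsets
`(read start − arm start, read end − arm end)`; a precursor-contained hit
failing that ⇒ `precursor_other` (reported but excluded from the count
matrix, since it is unstated whether such reads were counted anywhere);
any other genome hit ⇒ `novel_candidate` (exported as FASTA for an external
probabilistic caller; the caller itself is out of scope).

Design choices made where the method description was genuinely open:

- *Seed definition.* The seed is implemented as mature positions 2–8, the
  standard definition. The alternative reading that anchors matching at the
  3' end is not used: the isomiR variation these libraries document is
  3'-terminal, which is incompatible with demanding a perfect 3' anchor,
  and the ±3 nt offset cap already bounds end variation. The
  `max_offset = 3` cap itself is a package choice: it bounds isomiR calls
  and is consistent with the 17–27 nt read window around a 22 nt arm.
- *Multi-mappers.* A read eligible for `known_mir` at more than one locus is
  assigned to the locus with the smallest `|offset5| + |offset3|`; exact
  ties are flagged and excluded from counts. The method description is
  silent here; with 17–27 nt reads on a 50 kb reference ties essentially
  only arise from genuinely duplicated arms.
- *Coordinates.* 0-based half-open internally; GFF3 I/O converts to 1-based
  inclusive (miRBase dialect: `miRNA_primary_transcript` and `miRNA`
  features linked by `Derives_from`). Reads are matched on both genome
  strands and a `known_mir` call requires strand agreement with the
  annotated precursor.

The dominant read of an arm is the isomiR with the largest summed count
(ties: lexicographically smallest sequence, a deterministic tie-break);
unique-read counts per (arm, library) are reported alongside.

## Differential expression

The two phases are compared as two independent groups, as the original
analysis did, even though samples are paired — pairing enters only the
validation statistics. The stages:

1. **Size factors** by median-of-ratios: `s_j = median_i k_ij / g_i` over
   rows `i` with all-positive counts, `g_i` the geometric mean across
   libraries (a `poscounts`-style fallback exists for matrices where every
   row contains a zero). The literal ratio median is used (not the
   log-scale median), which matters only for even row counts.
2. **Dispersions** by method of moments on normalized counts:
   `alpha_i = max(0, (v_i − q_i * mean(1/s_j)) / q_i^2)` with `v_i` the
   pooled within-condition variance (the natural two-group reading of the
   variance), then a trend `a0/q + a1` fitted by least squares over rows
   with positive raw estimates, and the conservative
   `max(raw, trend)` rule. This mirrors the cited method's defaults; the
   original study names only the package it used.
3. **Exact test**: conditioned on the row total `K`, every split
   `(a, K−a)` is scored with NB probabilities parameterized by the
   condition-summed means `q0 * sum(s_j)` and variances
   `q0 * sum(s_j) + alpha * q0^2 * sum(s_j^2)`; the two-sided p-value sums
   the probabilities of splits no more probable than the observed one
   (with a 1e-8 relative tolerance for ties), rather than doubling one
   tail. `alpha = 0` (or a variance at or below the mean) falls back to
   Poisson, where the conditional distribution is exactly binomial. A row
   total of zero gives p = 1; all-zero rows are dropped before testing and
   the BH multiplicity `m` counts only tested rows.
4. **Fold changes** both as the ratio of mean normalized counts and as the
   difference of condition means of the variance-stabilizing transformation
   `w(k) = (2/sqrt(alpha)) * asinh(sqrt(alpha * k))`, rescaled by
   `sqrt(alpha)/log(2)` so that for `alpha * k >> 1` it approaches the
   plain log2 ratio. Note the regime: the VST approaches the log scale for
   *large* `alpha * k`; as `alpha -> 0` it degenerates to `2 * sqrt(k)`,
   so rows with near-zero dispersion use a shifted `log2(k + 1)` instead.
   A zero denominator yields a missing ratio with the VST difference still
   defined.

Two calibration facts the test suite pins down: under a null simulation the
procedure is slightly conservative (type-I error ~0.035 at nominal 0.05,
the price of the `max` dispersion rule), and with 10% of rows planted at
log2FC = 2 the BH-0.05 list keeps the empirical FDR at or below 0.10 with
every detected planted row pointing in the planted direction. One property
that does *not* hold exactly: multiplying one library's counts by a
constant is absorbed exactly by the size factors — normalized counts and
fold changes are invariant — but the exact test re-conditions on the new
raw totals, so individual p-values can move even though significance calls
do not.

## Pathway enrichment

The union target set of the query miRs keeps genes with a miTG score at or
above 0.7 (inclusive — strictness is not stated, and the conventional
reading of a "threshold of 0.7" admits equality) for at least one miR. The
score itself is consumed as an opaque, precomputed quantity; its internal
MRE/conservation weighting is deliberately not re-derived. The gene
universe is the union of all pathway genes, and targets outside it are
dropped before testing — the in-universe convention, recorded in the result
attributes. Pathways with fewer than 10 genes are excluded before testing.
Each remaining pathway is scored with the one-sided Fisher test, computed
as the hypergeometric upper tail `P(X >= overlap)`; results are ranked by
raw p, with no multiple-testing correction by default (matching how such
enrichment p-values are conventionally reported raw) and an optional BH
column.

## Clinical statistics

- **qRT-PCR abundance**: `2^-(Ct_target − Ct_reference)` against the RNU48
  small nucleolar RNA, assuming doubling amplification efficiency (the
  standard ΔCt convention; the efficiency is not calibrated here).
- **Exact rank tests**: the Wilcoxon signed-rank test drops zero
  differences, assigns average ranks to tied absolute differences, and for
  up to 25 usable pairs computes the exact two-sided p from the convolution
  of the 2^n sign-assignment null (doubling the smaller tail, capped at 1);
  the Mann–Whitney test enumerates the `choose(N, n_A)` rank assignments by
  dynamic programming with the same tie handling. Beyond the exact range
  both use the tie-corrected normal approximation with continuity
  correction. Because average ranks are half-integers at worst, both DP
  lattices run on doubled ranks, which keeps the arithmetic exact.
- **Power**: for the 12-pair design, paired differences are drawn from
  `N(effect_size, 1)` — "effect size 1" read as a standardized mean paired
  difference of one SD, the conventional input to this calculation — and
  the exact test is applied at alpha = 0.05; power is the rejection
  fraction over 50,000 replicates (Monte-Carlo SE ~0.16 percentage
  points). The simulation reproduces ~85–86% power. Continuous draws are
  almost surely free of ties and zeros, so the per-replicate p-value
  depends only on the positive-rank sum and is served from a precomputed
  lookup identical to the full test. One calibration subtlety: the exact
  test is discrete, so its true size at nominal 0.05 with n = 12 is
  ~0.0425, and the null rejection rate is checked against that analytic
  size rather than against 0.05 itself.
- **Vesicle fraction**: `1 − level(Triton+RNase)/level(RNase)` — the share
  of transcripts that RNase can degrade only after membrane disruption,
  i.e. the membrane-protected, vesicle-associated fraction. Raw values
  outside [0, 1] (possible with noisy assays) are clamped for reporting
  with the raw value preserved.
- **Correlation**: Spearman rho via average ranks; undefined (missing, with
  a warning) for constant input.

## Problem sizes and runtime

The shipped tests run the full pipeline at the study design (12 pairs,
50 loci) with ~2,000-read libraries, 200 × 500-row null replicates for
type-I calibration, and 50,000-replicate power runs; the complete suite
finishes in about two minutes on one core. These sizes are the package's
chosen operating points for exhaustive-oracle checking, not limits of the
implementation; `sim_config()` scales all of them.

## Known limitations

- Exact substring matching stands in for alignment; there is no tolerance
  for sequencing error in reads (by design, matching the zero-mismatch
  mapping strategy).
- The unpaired NB test ignores the pairing structure of the design,
  faithfully to the original analysis but at some cost in power.
- The dispersion trend `a0/q + a1` is fitted by unweighted least squares;
  no shrinkage or outlier refitting is attempted.
- Novel-miR discovery stops at exporting candidate reads; no hairpin or
  probabilistic scoring is performed.
- miTG scores and pathway membership are consumed as given; no live
  database retrieval exists.
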