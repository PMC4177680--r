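---
title: "Quantifying IES retention from developing-macronucleus sequencing"
author: "iesret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying IES retention from developing-macronucleus sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iesret)
```

# The measurement problem

In ciliates with separate germline and somatic nuclei, development of a new
somatic macronucleus (MAC) removes tens of thousands of short, single-copy,
non-coding Internal Eliminated Sequences (IESs) from the zygotic genome.
Every IES is bounded by 5'-TA-3' dinucleotides, one of which remains at the
somatic junction after precise excision. When a component of the excision
machinery is depleted before sequencing the developing MAC, some IESs stay
in place, and the sequenced DNA becomes a mixture of molecules that retain a
given IES and molecules that do not — including, unavoidably, DNA from
fragments of the old (maternal) MAC that is always fully excised.

`iesret` estimates, per IES, the fraction of sequenced molecules that retain
it, and tests whether that fraction exceeds what a control sample shows.

# Two references and one score

Reads are aligned both to the MAC assembly and to a "MAC+IES" assembly in
which every annotated IES is re-inserted immediately before its junction TA,
so each germline locus reads `...TA-body-TA...` and deleting `length` bases
at the lifted junction restores the MAC exactly (`build_mac_plus_ies()`,
`excise_all_ies()`; the package checks this round trip byte-for-byte).
Coordinates are 1-based and closed as in GFF3; the IES sequence includes its
leading TA, matching the convention that one TA is left behind by excision.
IESs are recorded on the forward strand only — excision is strand-symmetric
and the TA motif is its own reverse complement. Overlapping or nested IESs
are rejected in this version, since the retention statistic is defined per
independent junction.

At each IES, uniquely aligned reads (primary alignments with MAPQ at or
above `mapq_min`) are classified **at the element's ends only**:

* **IES⁻**: on the MAC reference, the read's matched bases cover the
  junction window — the junction TA plus `anchor` flanking bases,
  `2*anchor + 2` bp wide.
* **IES⁺**: on the MAC+IES reference, the read's matched bases cover the
  left boundary window (upstream somatic DNA | IES leading TA) or the right
  boundary window (IES end | retained somatic TA). Both windows have exactly
  the same width and structure as the junction window.

The retention score is `RS = IES⁺ / (IES⁺ + IES⁻)`, `NA` when no read
classifies.

## Why the IES⁺ tally is a per-boundary average

A retained molecule presents *two* classifiable boundaries per IES; an
excised molecule presents *one* junction. If every read touching either
boundary were summed, retained molecules would be sampled up to twice as
efficiently as excised ones — and less than twice for short IESs, where a
single read can span both boundaries. The resulting RS would overestimate
retention by a length-dependent factor, contradicting the design goal that
counting "at IES ends" removes length bias.

`count_boundaries()` therefore tallies the two boundaries separately
(deduplicating read identifiers within each boundary) and reports
`ies_plus` as the rounded mean of the two tallies, with half-to-even
rounding so the expectation is unbiased. Under this rule each boundary
window offers exactly `read_length - (2*anchor + 2) + 1` eligible read start
positions — the same number as the junction window — so the expected RS
equals the IES-bearing molecule fraction at every IES length. A read
spanning both ends of a short IES enters both boundary tallies, i.e. it
still counts exactly once in the averaged tally. A read that is classified
both IES⁺ and IES⁻ for the same IES is contradictory and is dropped
(reported in the `dropped` attribute). Mates of a pair are counted as
independent reads.

## Classifier parameters

* `anchor` (default 5 bp): matched bases required on the flanks of the
  boundary TA. It must exceed the 2 bp ambiguity of the shared TA — a read
  ending inside the TA cannot distinguish the retained from the excised
  form — with margin for sequencing errors. Larger anchors discard more
  reads without changing the expectation.
* `mapq_min` (default 1): excludes aligner-flagged multi-mappers (MAPQ 0),
  an aligner-agnostic proxy for "unambiguous alignment".
* `require_no_indel` (default TRUE): the boundary window must fall inside a
  single gapless matched run. With `FALSE`, matched runs abutting across an
  insertion are merged; a deletion still breaks the window.

Soft-clipped bases never count toward anchors: windows are evaluated on
CIGAR match (`M`) runs in reference space.

# Significance against a control

Counts, not scores, carry the evidence, so the test works on counts. For an
IES with control counts `(k_c, n_c)` and experimental counts `(k, n)`:

1. `control_upper` = upper endpoint of the exact two-sided Clopper–Pearson
   interval for the control proportion at confidence 0.95 (computed per IES,
   by beta-quantile inversion `qbeta(1 - alpha/2, k_c + 1, n_c - k_c)`;
   `k_c = n_c` gives 1).
2. One-sided binomial p-value `P(X >= k)` for `X ~ Binomial(n,
   control_upper)`.
3. Benjamini–Hochberg step-up adjustment over all tested IESs; adjusted
   p < 0.05 (configurable `fdr_threshold`) calls the IES significantly
   retained.

Using the control interval's *upper bound* as the null proportion makes the
test deliberately conservative: the control sample's own sampling noise is
absorbed before any retention is claimed. Two open choices were resolved as
follows. The control interval is computed per IES from that IES's own
control counts (per-locus coverage varies over orders of magnitude; a pooled
bound is available via `pooled_control = TRUE`). An IES with zero classified
reads in either sample is untestable and returns `NA` — it is excluded from
the number of tests rather than silently passed or failed.

`bh_adjust()` is authored in the package (step-up with enforced
monotonicity, capped at 1, `NA`s excluded from the number of tests and
preserved in place) and is cross-checked in the test suite against both a
brute-force step-up oracle and `stats::p.adjust`.

# The synthetic world

`simulate_genome()` and `simulate_reads()` generate data with the
statistical structure the analysis assumes, so every stage is testable
without downloads. The generator's defaults state that world:

* AT-rich genome, GC fraction 0.28.
* IES lengths from a mixture over the periodic peaks of the genome-wide IES
  size distribution — peaks every ~10 bp from 26 bp, first peak 26–32 bp
  holding roughly a third of elements, weights decaying to rare kb-scale
  elements (`default_ies_length_distribution()`). Every IES starts with TA
  and sits at a TA junction forced into the MAC sequence; junctions are
  evenly spaced with a junction-free margin at contig ends so boundary
  windows are uniformly coverable.
* 100 bp paired-end reads, FR orientation, insert 250 ± 30 bp, depth 25×,
  substitution errors at 0.005 per base (no indels in this version — the
  classification logic is exercised identically and the oracle stays
  simple), constant Q30 qualities.
* A molecule mixture: with probability `c` (the maternal-MAC contamination)
  a fragment comes from a fully excised maternal molecule; otherwise from a
  new-MAC molecule that retains each IES independently with its truth
  `retention_fraction` r. Retention is drawn per fragment, not per cell:
  RS is a read-level, per-locus statistic, and fragment independence is the
  minimal model that reproduces its sampling distribution. The expected
  IES-bearing fraction at a locus is therefore `(1 - c) * r`, which the
  pipeline's RS estimates consistently.

The paper-scale contamination fraction is not knowable from published
summaries — a mean RS of 0.77 under a knockdown that abolishes all excision
is *consistent with* c ≈ 0.23, and the test suite uses that regime — but c
remains a free simulation parameter.

Fragment starts are drawn uniformly along molecules. Positions inside an IES
exist only in molecules that retain it, which the sampler realizes by
rejection: a start falling inside IES k is accepted with probability
`(1 - c) * r_k`, so base-level coverage of IES interiors scales with the
retaining-molecule fraction while somatic coverage is uniform.

Besides FASTQ, the simulator writes "ideal aligner" SAM against both
references, derived from each fragment's known block structure: a read is
soft-clipped at any junction discontinuity (the longest reference-contiguous
run wins, minimum 15 matched bases, MAPQ 60), exactly as a short-read
aligner would treat a read crossing a sequence that is absent from the
reference. Substitution errors change reported base strings but never these
truth-derived alignments; classification uses only CIGAR and position, so
large runs can skip sequence emission (`emit_sequences = FALSE`).

What the generator does **not** emulate: indel and machine-specific error
profiles, PCR duplicates, paralogy-induced multi-mapping, coverage biases
(GC, mappability), imprecise chromosome-fragmentation breakpoints, and real
aligner heuristics. A green simulation test therefore establishes the
correctness of the counting and testing machinery under the stated
generative model — not robustness to every artifact of real libraries. The
boundary counter consumes any external aligner's SAM/BAM through the same
interface.

# Cohort analyses

* **Size groups** (`default_size_bins()`): 23 contiguous groups anchored at
  the printed features of the periodic size distribution — five peak groups
  26–32, 33–42, 43–52, 53–62, 63–72 bp; width-10 groups through 203–212;
  then 213–332, 333–532, 533–1032 and a final ≥ 1033 bp group. The exact
  edges behind the published 23 group counts are not recoverable from the
  printed anchors alone (five peak groups to 72 bp plus width-10 groups to
  332 bp already exceed 23 groups), so the binning ships as an explicit,
  configurable default that honours every printed anchor: 26–32 first, five
  groups to 72 bp, an edge at 332 bp, a last group beyond 1 kb, 23 groups
  in all.
* **Group summaries**: median and quartiles of RS per group, the proportion
  significantly retained, and a two-sided rank-sum (Mann–Whitney) test of
  each group against the previous one (exact for two groups of ≤ 50,
  normal approximation with tie correction otherwise). Stars encode the
  adjacent-group p-value: `*` p < 0.05, `**` p < 1e-10, `***` p < 2.2e-16 —
  a pure threshold function of the computed p-values.
* **Overlaps** (`overlap_sets()`): all exclusive intersection cells over the
  significant sets of several knockdowns (the cells partition the union)
  plus pairwise subset relations.
* **Replicate concordance** (`rank_correlation()`): Spearman rho via
  mid-ranked rank transform, p-value from the t approximation; exact ±1
  returns p = 0.
* **Feature association** (`compare_feature()`): rank-sum test for
  continuous features (GC content), chi-square on the 2×2 table for binary
  features (located within a gene — a caller-supplied annotation, not
  computed here); the effect direction is reported relative to the
  significant set. For a size-controlled comparison, restrict the input to
  one size bin before calling.

# Coverage-based sequence complexity

`contig_rpkm()` computes reads per kb of contig per million mapped library
reads; `covered_complexity()` sums the lengths (in Mb) of contigs longer
than 1 kb covered at ≥ 2 RPKM; `subset_not_covered_by()` selects contigs
below the cutoff in a control sample — germline sequence not collinear with
somatic chromosomes. Per-element coverage (`element_coverage()`, e.g.
transposon copies) uses an *external* library-size denominator — the
sample's reads mapped to the somatic reference — while contig complexity
uses the library's own mapped total; the two denominators are deliberately
distinct and explicit. Read counting is primary-alignment, mates
independent, consistent with the boundary counter. RPKM is recomputed, not
added, under any regrouping of contigs.

# Numerical choices and degenerate inputs

* Clopper–Pearson via `qbeta` is exact inversion; the suite verifies
  agreement with bisection on the binomial CDF to 1e-9 for all n ≤ 200.
* One-sided binomial p-values come from `pbinom` upper tails and match
  direct pmf summation to 1e-12; `k = 0` returns exactly 1.
* RS is kept at full floating precision; TSV output rounds to 3 decimals.
* `ies_plus` rounding is half-to-even, keeping the averaged tally unbiased.
* Ties in the rank tests are mid-ranked; adjacent-group tests are skipped
  for empty groups (n = 0 rows keep `NA` summaries).
* Zero-length contigs, empty references, non-ACGTN letters, duplicate
  contig names, junctions without TA, IESs not starting with TA, and two
  IESs at one junction all raise early, named errors; elements shorter than
  26 bp warn but are kept.
* Determinism: every stochastic step runs under a caller-supplied seed via
  an internal seed guard that restores the caller's RNG state; identical
  seeds give byte-identical FASTA/FASTQ/SAM/TSV outputs.

# Known limitations

* The classifier requires gapless matched coverage of a 12 bp window
  (default anchor); aligners that represent a retained short IES as an
  insertion rather than a soft clip yield the same classification, but
  exotic spliced or long-read alignments are out of scope.
* De novo IES discovery, germline assembly and alignment itself are out of
  scope; the IES reference set is an input, inherited from an external
  identification pipeline with its own false-positive rate (≤ ~4% for the
  published set), which the conservative control-bound test is designed to
  tolerate.
* The significance framework is one-sided (retention only) and does not
  model contamination inside the test; RS estimates `(1 - c) * r`, not r.
* Nested IESs (a short element inside a longer one) are rejected rather
  than resolved.
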