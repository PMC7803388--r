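---
title: "Integration-site calling and clonality verification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integration-site calling and clonality verification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intclone)
```

## The problem

Production cell lines for therapeutic proteins (typically CHO) acquire
their product gene by random integration of a linearized plasmid vector
into the host genome. Because two independent integration events
essentially never land on the same base, the set of vector–genome
junction coordinates is a fingerprint of the founding cell: all clones
descended from one transfected ancestor carry the same integration
site(s). Identifying those sites from targeted sequence-capture data —
fragments containing vector sequence are enriched by hybridization probes
against the vector, then sequenced — therefore both locates the transgene
and verifies clonality across multiplexed samples.

`intclone` implements the downstream half of that workflow. Its input
contract is the output of a standard upstream: adapter-trimmed reads
aligned with a local aligner (BWA-MEM) against the host genome assembly
*with the linearized vector appended as one extra named scaffold*, and
duplicates flagged (Picard-style, FLAG bit 0x400). The package consumes
SAM v1 text; it parses only the fields the method needs (mandatory
columns, `NM:i`, `SA:Z`).

## Junction detection from split reads

A read that physically spans an integration junction aligns in two
pieces: one on a genome scaffold, one on the vector scaffold. The aligner
reports one piece as the primary alignment, clips the rest (`S`/`H`
CIGAR operations), and records the partner placement in the `SA:Z` tag
(`rname,pos,strand,CIGAR,mapQ,NM;`). For each half the junction
coordinate follows from the SAM position (leftmost aligned base,
1-based) and the CIGAR:

* CIGAR begins with aligned bases, clip at the end — the junction is
  `pos + reference_span(CIGAR)`, where the reference span sums all
  reference-consuming operations (`M D N = X`);
* CIGAR begins with a clip — the reported position is already the first
  aligned base, i.e. the junction.

Counting `D`/`N` in the span (not just `M`) matters: a deletion inside
the aligned block shifts the reference coordinate, and ignoring it would
misplace the junction by the deletion length for gapped split
alignments. This generalization is deliberate and is covered by a
per-base CIGAR-expansion oracle in the test suite.

Evidence is accepted only when **both** halves of the split pass
`MAPQ > 30` and `NM < 4` (strict inequalities, the published operating
point). Filtering both halves is the conservative reading of the
procedure — the decoy chimeras the filter exists to remove are exactly
those with one confident and one dubious half. A record with no NM tag
fails the filter: edit distance that cannot be assessed is not assumed
to be zero. Secondary alignments (0x100) are ignored; supplementary
records (0x800) describe the same chimera as their primary's SA tag, so
evidence is deduplicated by (read, mate, junction) and never
double-counted.

Support is tabulated per unique junction key (scaffold, genome position,
vector position, vector end) as the number of *distinct read names*: when
both mates of a pair span the same junction the pair counts once. A
junction is called an integration site at `support >= min_support`.
"A minimum of N" is read as `>= N`; the boundary is exact and tested
(14 supporters are rejected under the deep threshold of 15, 15 are
called). Two thresholds are exposed as presets reflecting the two
published operating points: `deep` (15; a single deeply sequenced
library) and `multiplex` (5; barcoded libraries pooled before capture,
each with far fewer reads).

Each insertion exposes up to two junctions — the left and the right end
of the linearized vector. The vector-side junction coordinate is
compared with the vector midpoint to label the end; this supports
reporting "both ends ~30 bp apart" structures without sequence-level
terminus annotation.

### Merging near-identical positions

By default `merge_window = 0`: junctions are tabulated at exact
positions, matching the observation that true junctions agree at the
base level across samples. Microhomology at a junction can, with some
aligners, split support across a few bp; a configurable window merges
candidates on one scaffold and vector end whose positions chain within
the window *before* thresholding (supporters unioned; the merged
position is the support-weighted mode, ties to the smallest coordinate).
Merging is off by default because it was not part of the original
procedure.

## Capture statistics

Each unique (duplicate-excluded) read pair is classified once: on-target
if any mate's primary or SA alignment touches the vector scaffold,
otherwise genome-only, otherwise unmapped. The three categories
partition the library exactly, which is asserted rather than assumed.
The enrichment ratio (vector / non-vector) is reported both pair-based
and read-based because the field's usage is ambiguous; the pair-based
number is the headline. Degenerate inputs are defined: an empty stream
reports zeros with a `no_pairs` flag, and an all-on-target library
reports an infinite ratio (serialized as the string `"Inf"` in JSON).

## Clonality by site-set comparison

Two sites match when scaffold and vector end agree and positions differ
by at most `tolerance` bp (default 0, for the base-level identity
observed in practice; raise it for noisier aligners). Matching is
one-to-one. Sample pairs are labelled `identical`, `subset`, `partial`
or `disjoint`, with a Jaccard index `matched / (|A| + |B| - matched)`.

Lineage groups are connected components of the graph linking samples
that share at least `min_shared` matched sites (default 1 — a single
shared junction is already strong evidence of common ancestry, since
independent integrations essentially never collide). A *subset*
relation does not break a clonality verdict: the documented
interpretation is a locus whose support fell below the calling threshold
in the shallower sample, and the component construction groups such
samples with their lineage automatically.

Within a sample, junction pairs on one scaffold are annotated:

* opposite vector ends within `end_pair_distance` (default 500 bp,
  covering the observed ~30 and ~100 bp separations with margin) are the
  two ends of one insertion and collapse to one locus;
* other pairs within `link_distance` (default 10 kb, covering observed
  extra junctions 1 and 4.7 kb downstream of a locus) are flagged
  `linked` — likely local rearrangement or duplication, not an
  independent event — and excluded from the independent-locus count
  while staying in the site table.

The locus count is the number of connected components of the sites under
these two relations.

## The simulator

Real capture data cannot ship with the package, so the simulator emits
alignment-level fixtures directly as SAM — no aligner in the loop, which
keeps tests hermetic and byte-reproducible under a fixed seed. For each
planted junction it constructs primary-with-SA split pairs whose
positions, clip lengths and SA entries are mutually consistent (the test
suite checks query-length conservation and in-bounds placement), with
MAPQ 60 and NM 0 in error-free mode. Around each junction it places
genome-only pairs at exponentially distributed distances
(`capture_decay`, default 0.01/bp), reproducing the decaying pileup that
capture probes on the vector produce; it also emits vector-only,
genome-only and unmapped background pairs, duplicate-flagged copies
(`dup_rate`), and decoy chimeras with configurable MAPQ and support.

Defaults mirror the study conditions: 100 bp paired-end reads from
250 bp fragments for the multiplexed lineage presets, 250 bp reads from
500 bp fragments for the deep-capture preset. Preset structures encode
the described integration landscapes: `sh87` (three loci × both ends =
six junctions, support 25), `lineage_A` (both ends 30 bp apart),
`lineage_B`/`_D` (one end each), `lineage_C` (one called end plus one
whose vector side is unmappable — modeled abstractly by a
`suppress_sa` truth that emits genome-side-only alignments, standing in
for a vector half that maps ambiguously into a duplicated vector
element), and `lineage_E` (three loci on three scaffolds, one with both
ends 100 bp apart). `cohort_presets()` assembles the 32-sample
multiplexed cohort (13 lineage-A lines plus a duplicate run, 3 B, C-1,
D-1, 13 E) with the sample-specific deviations: an extra linked junction
1 kb downstream in A-2, 4.7 kb downstream in E-2/E-10, and one junction
at support 3 (below the multiplex threshold) in E-1.

What the simulator does **not** model: real base composition and repeat
structure (sequences are i.i.d. uniform), base-call errors and quality
strings, concatemer structure inside the integrated vector, and genuine
mapping ambiguity (MAPQ is assigned, not computed). Passing recovery
tests therefore demonstrates the correctness of the coordinate
arithmetic, filtering, tabulation and grouping logic on well-formed
aligner output — not robustness to aligner pathologies on repetitive
genomes.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely on simulated
fixtures: the largest is the 32-sample cohort at roughly 150–400
alignment records per sample (a few thousand SAM records total), which
the full pipeline processes in seconds. Threshold sweeps use 30
junctions across 30 scaffolds (support 1..30) and 9–11 single-junction
fixtures for the MAPQ/NM boundaries. All randomness flows through
explicit seeds; generators save and restore the caller's RNG state, and
every output table is deterministically sorted by (scaffold, position,
vector end), so reruns are byte-identical.

## Known limitations

* Vector-end labelling by midpoint comparison assumes junction reads
  anchor near a vector terminus, which capture probe placement
  encourages but does not guarantee for heavily rearranged insertions.
* Concatemer and complex rearrangement structure inside an insertion is
  out of scope; such events surface only as extra linked junctions.
* BAM input is not parsed natively; convert with `samtools view -h`.
  Text SAM is the canonical, tested surface.
* The clonality verdict is only as good as the per-sample calls: a
  lineage whose every junction fails capture or mapping in *all* samples
  is invisible, and the method cannot distinguish that from true absence.
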