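---
title: "pirnakit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pirnakit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`pirnakit` implements a small-RNA sequencing analysis for insect
libraries in which two populations dominate: ~22 nt siRNAs and ~24–32 nt
PIWI-interacting RNAs (piRNAs) that silence transposable elements (TEs),
including horizontally transferred transposons (HTTs) such as SPIN, hAT,
OC1 and ET. The package covers everything downstream of genome
alignment: read classification, fractional quantification,
sliding-window piRNA-cluster discovery, strandness calls, sense/antisense
TE counting, and the ping-pong, phasing and nucleotide-bias signature
statistics. Adapter trimming, alignment and repeat discovery are
upstream tools' jobs and are out of scope; the alignment enters as a
BED6+2 table carrying, per mapping, the read sequence and its genomic
mapping multiplicity (the upstream aligner is assumed to report at most
50 mappings per read, and that cap is enforced at parse time).

## Coordinate and strand conventions

All internal coordinates are 0-based half-open; BED is the only
interchange dialect. This removes the off-by-one ambiguity that plagues
overlap and distance definitions. The 5' end of a `+` strand read is
`start`; of a `-` strand read, `end - 1`. Read sequences are stored as
the cDNA of the aligned strand, so the first character of `sequence` is
always the biological 5' nucleotide.

Two consequences used throughout:

* **5'–5' overlap** between a `+` read and a `-` read is
  `k = (minus_5' - plus_5') + 1`, counted only when both reads cover the
  shared register (`k` at most either read's length). The ping-pong
  hallmark is an excess at `k = 10`.
* **Phasing distance** between same-strand reads is the genomic gap
  `d = 5'(downstream) - 3'(upstream)` with half-open ends, so
  head-to-tail reads give exactly `d = 0`. The source wording for this
  statistic is ambiguous about direction ("5' to 3'" vs "3' and 5'
  ends"); we implement the Han-style 3'→5' gap, under which `Z0`, the
  z-score at distance zero, measures phased production. All same-strand
  ordered pairs with `d` in `[0, max_distance]` are tallied (not only
  nearest neighbours); with the leave-one-out z-score this makes the
  statistic insensitive to overall read density.

## Apportioning

Multi-mapping reads are fractionally counted: each mapping carries
weight `1/mapping_count`, and each mapping's weight is further divided
by the number of annotation records it overlaps. The invariant checked
at every stage (and logged by `run_pipeline()`) is conservation: summed
apportioned mass over all groups, unassigned included, equals the number
of distinct read ids. Pair statistics (ping-pong, phasing) weight each
pair by the product of the two mappings' weights, which extends the
apportioning rule to pairs and makes the z-scores invariant to
duplicating every mapping with halved weight.

## Read classification

Classification is exclusion-first: any overlap with a miRNA, rRNA,
snRNA, simple repeat or low-complexity record removes a read from the
piRNA set (these are contamination filters, so the overlap test is
strand-blind). Among the remaining reads, TE-overlapping reads of
24–32 nt are piRNAs and 18–23 nt are siRNA candidates. The upstream
description of the piRNA window is internally inconsistent (24–32 in the
definition, 24–30 in one filtering step); the package defaults to 24–32
and exposes both bounds (`pirna_range`). When a read overlaps several
excluded classes the reported label follows a fixed precedence
(miRNA > rRNA > snRNA > simple repeat > low complexity) purely for
reproducibility. "Unassigned" means overlapping no annotation record at
all.

## Cluster discovery

`call_clusters()` scans each scaffold with windows of 5 kb sliding by
1 kb and retains a window when both criteria hold:

* read density, counted as 5'-end positions per kb, **strictly greater**
  than 5 reads/kb;
* at least 12% of the window's bases covered by read intervals
  (**inclusive**).

Retained windows are unioned, and unions separated by **strictly less**
than 20 kb are combined. The comparison directions follow the defining
wording exactly and are pinned by dedicated fixtures in the test suite.
Two deliberate choices where the source is silent: a read belongs to a
window by its 5' end (density and coverage are therefore genuinely
different criteria — a pile-up of thousands of reads at one miRNA locus
fails the 12% coverage test and never becomes a "cluster"), and windows
are clipped at scaffold ends with the actual window size used in both
criteria, avoiding edge inflation. Calling uses uniquely mapping
piRNA-class reads (`unique_only = TRUE` enforces this). Clusters are
ranked by apportioned read support and named `RPCL1, RPCL2, ...`;
support ties are broken by genomic position so output is independent of
read order. Cluster RPM uses apportioned counts by default; with unique
reads the distinction from integer counts vanishes.

Strandness uses the 75% rule: a cluster (or the TE-fragment orientation
inside it) is `plus`/`minus` when at least 75% of its supporting reads
(records) lie on that strand, `unbiased` otherwise — the boundary counts
as biased because "less than 75%" defines the unbiased class.

Raising `min_density` or `merge_gap` never increases the number of
clusters *provided* inter-cluster background is itself sub-threshold; a
supra-threshold bridge between two blocks can legitimately split when the
bridge drops out. The test suite exercises the invariant in the regime
where it holds.

## Signature z-scores

No closed-form null is given for the overlap histograms in the source
analysis, so the package uses the common leave-one-out background:
`z(k) = (counts[k] - mean(counts[-k])) / sd(counts[-k])`. A degenerate
background (zero standard deviation, e.g. all counts zero) reports
`z = 0` with a `degenerate` flag rather than an infinity. The focal
statistics are `z(10)` for ping-pong and `Z0 = z(0)` for phasing.
"Paired" piRNAs are reads with at least one opposite-strand partner at
any 5'–5' overlap in `[1, max_overlap]`; the share of pair mass at
exactly 10 nt is reported separately, so both the broad and the
register-specific readouts are available.

## The synthetic-data generator

`simulate_genome()`/`simulate_library()` define the study conditions the
tests and the acceptance script run under. Defaults, chosen once to
mirror a scaled-down embryo-like library: a 700 kb two-scaffold genome;
three non-overlapping uni-strand clusters (60 kb total) whose TE
fragments (five resident families, ~0.8 fragments/kb, half on each
strand) are stamped from per-family consensus sequences; dispersed
full-length copies outside clusters as multi-mapping targets; HTT
insertions at fixed positions with OC1 the most numerous and a minority
inside clusters; five miRNA loci and one rRNA/snRNA/simple-repeat/
low-complexity locus each; 10,000 reads with length modes 22/28 nt
(weights 0.35/0.65, ±1 nt jitter); 30% of 28 nt-mode cluster reads in
ping-pong pairs at an exact 10 nt 5'–5' overlap; 30% of the remaining
28 nt-mode reads in head-to-tail phased trails of 2–5 reads; 1U bias
0.8, 10A bias 0.6, antisense fraction 0.7, multi-mapping fraction 0.15,
decoy regions at 2 reads/kb (safely below the caller's 5/kb cutoff).

Mechanistic choices worth knowing:

* **Uni-strand geometry.** Independent cluster reads sit on the cluster
  strand; whether a read is sense or antisense to a TE is decided by the
  orientation of the fragment it falls in, selected to match the
  configured antisense fraction. This is what makes clusters uni-strand
  while still producing both sense and antisense piRNAs, the central
  structural feature of the system being modelled.
* **Pair geometry.** The `+` strand mate's 5' end sits `overlap - 1` nt
  upstream (in `+` coordinates) of the `-` strand mate's 5' end,
  whichever mate is sense relative to the TE. The overlap length is a
  free parameter (`pingpong_overlap`) because the ~20 nt overlap
  observed for some HTT piRNA pairs has no established mechanism; the
  generator can emulate the register without asserting one.
* **Bias realization.** Base biases are written into the genome as
  per-base constraints *before* sequences are extracted, first-wins on
  conflicts, so `sequence == genome slice` (reverse complemented on `-`)
  holds exactly for unique mappers and biases can be measured from
  either side. With probability `u1_bias` a read's first base is set to
  U, otherwise it is drawn uniformly from A/C/G — this makes the
  parameter equal to the expected position-1 U frequency, i.e.
  identifiable; likewise `a10_bias` over C/G/U. A ping-pong antisense
  mate receives no constraint of its own: its first base is the
  complement of the sense mate's 10th, exactly as in the biology, so the
  generator realizes the 1U/10A duality rather than double-writing one
  base pair. Overlapping reads can still collide on a constrained base;
  dense configurations therefore realize a slightly attenuated bias,
  and the bias-recovery tests use clusters sized (200 kb for 10,000
  reads) so the attenuation stays well inside the ±0.03 recovery band.
* **Multi-mapping** duplicates an independent TE read at 2–4 copies of
  its family at the same consensus offset (possible because all copies
  of a family are stamped from one consensus). Multi-mapped reads carry
  no bias constraint and take their sequence from their primary locus;
  another read's constraint can make the other loci differ by a base or
  two, mirroring the mismatches the upstream aligner tolerates.
  Bias-recovery configurations set `multimap_fraction = 0`.
* `pingpong_fraction` and `phasing_fraction` are defined over 28 nt-mode
  cluster reads (pairs first, trails from the remainder), since those
  are the piRNA-mode reads the signatures describe.

What the generator does **not** emulate: sequencing error, adapter
artifacts, quality scores, TE sequence divergence/age structure, copy
number variation between samples, and genuine transcriptional read-through
at cluster boundaries. Passing tests therefore demonstrate that the
implementation computes its statistics correctly on data with the assumed
structure, not that the statistics are robust to every artifact of real
libraries.

## Problem sizes

The bundled analyses and tests run at deliberately desk-scale sizes:
genomes of 0.1–0.7 Mb, libraries of 500–10,000 reads, 50-instance
oracle sweeps and 100-seed null distributions. These sizes give the
detection statistics comfortable power (planted z-scores exceed 10 at
n = 10,000) while keeping the whole suite in the minutes range. Against
a full dataset (tens of millions of reads, a >700 Mb genome) the same
code paths apply unchanged; only `call_clusters()`'s per-scaffold
coverage vectors are worth watching for memory on very long scaffolds.

## Known limitations

* The caller treats scaffolds independently and has no assembly-gap
  awareness; a cluster interrupted by a gap is reported as two.
* Dual-strand/bidirectional clusters are not modelled as a class — the
  system under study shows no unambiguous ones — so `strandness` is the
  only strand descriptor.
* `paired_fraction` counts any 5'–5' overlap in `[1, max_overlap]` as
  "paired"; restricting to the 10 nt register is available through the
  histogram instead.
* RPKM for TE families aggregates summed copy lengths per family;
  per-copy RPKM is not currently exposed.
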