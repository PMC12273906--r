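---
title: "Detecting eccDNA in rolling-circle concatemer reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting eccDNA in rolling-circle concatemer reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Extrachromosomal circular DNA (eccDNA) molecules are released from
chromosomes by transposon mobilization, recombination between repeats, and
DNA repair. Rolling-circle amplification (RCA) with phi29 polymerase turns
each circle into a long linear concatemer in which the circular unit — the
*monomer* — is tandemly repeated. After high-accuracy long-read sequencing,
a read covering more than one full round of the circle is direct,
reference-free evidence that the source molecule was circular, and the
repeat structure itself yields an accurate consensus of the monomer.

rollcirc implements this idea as a reusable pipeline: read filtering, tandem
period detection, rounds estimation, monomer consensus, canonical circular
form, genome/TE/CDS annotation, window and TE-group quantification,
non-redundant clustering, and the inferential layer used to interpret eccDNA
populations (superfamily enrichment, condition comparisons, track and
fold-change correlations, inverted-repeat overlap, centromeric partition).

## Period detection and rounds estimation

A concatemer read of length $L$ built from a monomer of length $p$ contains
$r = L/p$ rounds. `estimate_period()` proposes candidate periods from the
distance spectrum of repeated k-mer anchors (k = 13 by default): identical
13-mers recur at multiples of the period, so the modal distance between
consecutive occurrences sits at the period itself. Each candidate is then

1. *refined* by pinning the second occurrence of the read prefix with a
   banded pattern-global alignment, iterated to a fixed point — this turns a
   candidate that is off by a few bases into the exact spacing; and
2. *verified* by aligning up to three later period-length segments against
   the first; the candidate is accepted only if the mean identity reaches
   `identity_floor` (default 0.90).

When a period $p$ verifies, its integer fractions $p/2, p/3, \dots$ down to
`min_monomer` are tested first and the smallest verifier wins, so a doubled
monomer is never reported. Reads shorter than about 600 bases are scanned
exhaustively instead, which makes tiny hand-built cases exact. Homopolymer
and microsatellite pseudo-periods fall below `min_monomer` (default 50 bp)
and therefore return "aperiodic" — a deliberate floor, since such reads
carry no usable circularity evidence.

Rounds are reported as $L/p$ with the *refined* period, so error-free reads
that are exact integer multiples of their monomer give exactly integral
rounds. Only calls with rounds strictly greater than 1 are retained (the
threshold is exposed as `min_rounds`); a read of exactly one round is
indistinguishable from a linear fragment and is never called.

## Consensus by majority vote

`deconcatenate()` slices the read into period-length segments, aligns each
later segment (and the fractional trailing segment) to the first with a
banded ends-free alignment, and votes per template column. Ties are broken
by the highest supporting base quality, then by the first segment's base.
Insertions relative to the template are adopted when a plurality of covering
segments agree on the same inserted string — this restores bases that a
sequencing deletion removed from the template copy and is what keeps the
consensus length within a couple of bases of the true circle even at 1%
read error. The alignment band grows with the square root of read length
because insertion/deletion drift across a read is a random walk, not a
linear accumulation.

## Canonical circular form

Two reads of the same circle generally start at different rotation phases
and possibly on opposite strands. `canonicalize()` maps every monomer to
the lexicographically least string over all rotations of both strands,
computed with Booth's linear-time least-rotation algorithm; the brute-force
enumeration over all $2L$ rotations serves as the test oracle. All
cross-read comparisons (clustering, deduplication) operate on this form.

## Annotation

Monomers are mapped to the genome, TE and CDS sequence databases by a
built-in exact-k-mer-seeded banded aligner designed for desk-scale data:
shared 13-mers propose diagonal clusters, each cluster is verified by a
banded alignment, and hits are reported in the standard 12-column tabular
dialect (1-based inclusive coordinates, `s_start > s_end` on the minus
strand). Hits are retained at identity >= 90% over >= 100 bp; these
thresholds act as the significance surrogate for this aligner, and the
`e_value` column is reported as 0. Externally produced tabular hits can be
supplied instead, in which case the conventional e-value cutoff (1e-50) and
a one-HSP-per-subject rule are applied verbatim. Karlin–Altschul statistics
are deliberately not reimplemented.

Because a monomer's phase is arbitrary, queries are *doubled* before
seeding (`circular = TRUE`), so a locus split by the rotation junction is
recovered as one contiguous alignment; query coordinates are reported
modulo the monomer length. Without this, a rotation that leaves a remainder
shorter than the 100 bp retention floor would silently lose coverage.

Per monomer, the annotation layer derives:

* **origin class** with the priority TE > CDS > intergenic. The underlying
  per-database tallies overlap (a monomer can hit TE and CDS databases);
  both the exclusive classes and the overlapping tallies are reported, since
  the denominator convention differs between the two views.
* **TE completeness**: *partial* when the monomer is shorter than its TE
  (the length rule), *full* when it is at least as long **and** the
  alignments cover >= 95% of the TE. The coverage guard is this package's
  addition: a long eccDNA merely longer than an unrelated TE must not be
  called full. The threshold is configurable.
* **single-event status**: hits on one chromosome/strand merged within
  `merge_gap` (default 100 bp); the monomer is a single event iff one merged
  locus covers >= `cover_fraction` (default 0.9) of it. The merge re-joins
  the rotation-phase split; chimeric circles keep two distant loci and fail
  the coverage test. Both defaults are package choices, exposed as
  parameters.
* **window**: the best hit's midpoint binned into half-open windows
  (default 100 kb; the bundled toy fixture uses 20 kb). Assignment by
  midpoint is a package choice — the alternative of counting every
  overlapped window is available by using the full hit table.

## Quantification

Two distinct denominators coexist and are kept explicit to prevent silent
mixing:

* window profiles: `counts per window / total eccDNA reads x 100` per
  replicate — so per-sample normalized windows sum to 100 times the mapped
  fraction;
* TE abundances: `TE-derived eccDNA reads / total CCS reads x 100` —
  family values sum exactly to their superfamily's value.

Fold changes between conditions are ratios of normalized values with an
optional pseudocount; a zero denominator yields `NA` with a warning rather
than an error, because a zero abundance is legitimate biology while a zero
manifest total indicates corrupt input (and is an error).

## Clustering

`cluster_monomers()` is greedy incremental clustering in the cd-hit style:
sequences visited longest-first (ties by id, so repeat runs are
byte-identical), each joining the first cluster whose representative reaches
the identity threshold (default 0.9) over the shorter sequence's length.
Identity is computed on canonical circular forms, so rotation phase and
strand can never split a cluster — a deliberate improvement over naive
linear clustering of circular molecules. A shared-13-mer prefilter skips
hopeless alignments. Word-filter heuristics of the wrapped tool are not
reproduced; alignment-verified greedy clustering is the contract.

Cluster statistics report the singleton fraction (redundancy) and the
single-event cluster fraction (genomic continuity of representatives)
*separately*: the two concepts are often conflated, but they answer
different questions and need not agree.

## Statistics

* **Enrichment** of eccDNA counts per TE group against the group's genomic
  composition uses the two-sided exact binomial test; brute-force pmf
  summation is the test oracle at 1e-12. Composition can be counted by
  element or by bp (element count is the default; both are computed).
  Multiple testing defaults to Benjamini–Hochberg; `correction = "none"`
  reproduces bare p < 0.05 reporting.
* **Group comparisons** use the Welch t-test for two groups (robust at
  n = 3) and one-way ANOVA for three or more.
* **Correlations** of window profiles with genomic tracks are Pearson over
  inner-joined windows, with explicit NA on zero variance.
* **Inverted-repeat overlap** counts a monomer as LIR-derived when its best
  locus overlaps any LIR interval by >= 1 bp (configurable).
* **Centromeric partition** tests, per family, the eccDNA centromeric share
  against the family's genomic centromeric copy fraction with an exact
  binomial test. The machinery generalizes to any user-supplied locus
  labeling; no age-based copy split is implemented because no usable
  criterion is defined for it.

## The synthetic-data module

The simulator generates what the pipeline needs to be testable end-to-end
without downloads: a toy genome (default two chromosomes; a single central
centromere interval per chromosome) with planted full-length TE copies that
are mutated descendants (8% substitutions) of per-family consensus
sequences, biased 5x into the centromere; CDS intervals in the remaining
space; circle populations drawn from TE (full and partial), CDS and
intergenic loci plus a small chimeric minority; and RCA reads with uniform
rotation phase, real-valued rounds (fractional last repeat — RCA does not
stop at integer multiples), and i.i.d. errors split 8:1:1 between
substitutions, insertions and deletions, the substitution-dominated profile
of high-accuracy consensus reads.

The default circle length model is a truncated lognormal with
`meanlog = log(3347)` and `sdlog = 0.436`, i.e. median ~3.35 kb and mean
~3.68 kb on the 0.5–22.4 kb range — the scale reported for plant leaf
eccDNA populations, which the simulator treats as its reference condition.
The default `min_read_length` is 3000, mirroring the insert-length filter
used on production circular-consensus data; the bundled toy fixtures use
200 because toy circles are smaller. Flat per-base qualities are emitted at
the Phred value implied by the configured error rate. Organellar
contaminant circles are not simulated.

What the simulator does *not* emulate: polymerase kinetics and quality
heterogeneity, chimeric adapter artifacts, barcode demultiplexing,
context-dependent error profiles, and realistic genome repeat structure
beyond the planted TE families. Passing tests therefore demonstrate the
correctness of the algorithms under controlled conditions, not performance
on any real library.

## Numerical and design choices

* Coordinates are 0-based half-open internally; GFF3 is written 1-based
  inclusive and BED half-open, with all conversions in one I/O layer.
* The alignment kernel is a banded dynamic program with linear gap cost
  (match 2, mismatch -3, gap -4) and three modes (global, ends-free,
  pattern-global); bands are sized from the expected indel drift.
* Consensus ties: highest supporting quality, then the template base, then
  alphabetical — fully deterministic.
* Best-hit ties: bit score, e-value, alignment length, then lexicographic
  subject/coordinate order — fully deterministic.
* Greedy clustering is order-dependent by nature; the fixed visiting order
  makes it reproducible rather than order-free.
* All stage randomness derives from one master seed; repeat runs are
  byte-identical on all data outputs.
* How fractional rounds interact with the retention rule is genuinely
  underdetermined (is 1.4 rounds circular evidence?); rollcirc requires
  rounds strictly greater than `min_rounds = 1` and exposes the threshold
  rather than hard-coding an answer. Note that the segment-based detector
  needs two full rounds to verify a period, so calls below 2.0 rounds do
  not arise from it in practice.

## Problem sizes

The test suite and the acceptance script run the standard synthetic suite
at desk scale: 150–200 kb toy chromosomes, 200-circle populations
(0.5–5 kb for caller stress tests, the full default length model for
population statistics), 1% read error, and 1000-replicate Monte-Carlo
calibrations for the exact binomial layer. These sizes were chosen so the
whole suite exercises every code path in minutes on a laptop while keeping
Monte-Carlo standard errors well inside the asserted bounds.

## Known limitations

* Near-duplicate circles that differ by sequencing error *and* happen to
  canonicalize to different rotation phases can fall into separate clusters;
  exact rotations and reverse complements always co-cluster.
* The built-in aligner is for desk-scale databases (megabases, not
  gigabases); production-scale mapping should use an external aligner whose
  tabular output feeds `read_alignment_hits()`.
* E-values are not computed by the built-in aligner; identity/length floors
  stand in for them and are clearly labelled.
* Period detection assumes one dominant tandem structure per read; nested
  or mixed concatemers yield the smallest verifying period.
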