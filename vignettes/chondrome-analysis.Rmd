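---
title: "Comparative analysis of plant mitochondrial genomes with chondromics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of plant mitochondrial genomes with chondromics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondromics)
```

## The problem

Plant mitochondrial genomes (chondromes) are large, circular, spacer-rich
molecules whose comparative annotation answers a recurring set of
questions: how much of the genome is coding versus intergenic, where do
the pseudogene fragments littering the spacers come from, how much RNA
editing does expression require, which repeats could mediate
recombination, and how scrambled is the gene order relative to other
species.  `chondromics` implements that survey as a reusable, tested
pipeline.  Because the published genomes behind such surveys are hundreds
of kilobases and live in external databases, the package also contains a
first-class synthetic-genome generator: every structure the pipeline
detects can be planted with known coordinates, so each stage is tested
against ground truth rather than against another implementation.

## Genome model and partition accounting

A genome is a circular (or linear) DNA string plus strand-aware gene
features; each feature carries ordered exon intervals (transcription
order), cis- or trans-spliced group II intron records, a pseudogene flag
and a copy index for duplicated genes.  Coordinates are 0-based half-open
internally and 1-based inclusive in reports and GenBank I/O — the former
avoids off-by-one arithmetic, the latter matches the convention every
GenBank user expects.  Introns are named `geneiNNNgK` (host gene,
insertion position in a reference coding sequence, intron group), e.g.
`nad1i728g2`.

Partition statistics classify every position exactly once with priority
exon > intron > spacer.  Published tables do not state how overlapping
annotations were counted, so the priority rule is our choice and reports
carry it.  Two further conventions, also choices where the literature is
silent: pseudogene-flagged features count as spacer (their sequence is no
longer under coding constraint), while duplicated rRNA/tRNA copies count
toward the gene fraction (they are intact genes).  `N` bases are allowed
and excluded from the AT-content denominator.  The partition identity
`exon_bp + intron_bp + spacer_bp = genome_bp` is asserted for every
genome the test suite touches, and all statistics are invariant under
rotation of the circular origin.

## Pseudogene archaeology

Fragments of functional genes in intergenic spacers are found by seeded
local alignment, the same shape of search as the BLAST scans used in
annotation practice: exact 11-mer seeds between query and spacer anchor
candidate windows, each window is refined with Smith–Waterman (match +1,
mismatch −1, gap open −2, gap extend −1), and hits are kept when they
reach 50 bp and 70% identity.  Queries comprise the spliced
(exon-joined) and unspliced (genomic) form of every functional gene, so a
fragment can be recognised either as a reverse-transcribed, spliced mRNA
copy or as an unspliced duplication.  Three thresholds matter:

* `min_len = 50` bp — the conventional reporting floor for spacer
  fragments.
* `min_identity = 70`% — guards against low-complexity chance hits; the
  published surveys state only the length rule.
* `min_score = 30` (matches minus penalties) — the analogue of BLAST's
  expectation cutoff.  Length and identity floors alone still admit an
  occasional 50 bp alignment at barely 70% identity between unrelated
  sequences once hundreds of kilobases are scanned; a raw-score floor of
  30 is far below the score of any genuine fragment at the identity floor
  (a 100 bp hit at 72% scores 44) yet above what random local alignments
  reach in a genome of this size.

Overlapping hits from the same parent merge into one fragment; the
retroposition call is then purely structural: a fragment crossing an
exon–exon junction without intron sequence is `retroposed_spliced`, one
retaining intron sequence is `unspliced_copy`, and a fragment inside a
single exon is `single_exon_uninformative`.  Origin classification uses
uncorrected p-distances on locally aligned columns against the functional
copy and an ortholog panel, with a margin of 0.02 substitutions/site and
a 50-column overlap floor; fragments are short, so a model-corrected
distance would be unstable.  tRNA-derived fragments are reported but, as
in the field's practice, excluded from origin analysis — tRNAs are too
short and conserved for the distances to mean anything.

## RNA editing

Without cDNA evidence, editing is inferred two ways.  Codon
reconstitution records the edits the genomic sequence alone makes
obligatory: an ACG first codon implies a C-to-U start-creating edit; each
internal genomic TAA/TAG implies a U-to-C stop-removal; a CAA or CGA
final codon on a CDS without genomic stop implies a C-to-U stop-creating
edit.  GTG is accepted as a genomic start for genes known to use it
(`rpl16` by default).  An internal TGA is flagged rather than "edited":
no single C↔U change restores it, and the published event inventories
contain no such case.

The comparative predictor aligns the translated CDS globally (BLOSUM62,
gap open 10, extend 0.5) to an unedited reference protein and, for every
aligned codon that does not encode the reference residue, finds the
minimal set of C↔U substitutions that would.  Ties are broken toward
more C-to-U — the overwhelmingly dominant direction in plant organelles.
Codons unexplainable by C↔U changes contribute nothing, as do gap
columns.  This is a deliberately simple surrogate for dedicated
predictors such as PREPACT, whose windowed scoring is not reproducible
from published descriptions; the per-gene numbers of such tools are
therefore context, while the aggregation arithmetic (per-reference column
sums) is exact and tested.

## Repeats and microsatellites

The exact engine finds all maximal repeated pairs at or above 100 bp,
forward–forward (direct) and forward–reverse-complement (inverted), by
seeding on identical 32-mers and extending each seeded diagonal to its
maximal match, with modular arithmetic for circular genomes (any maximal
repeat ≥ 100 bp contains an exact 32-mer, so the seeding is complete).
Tandem, self-overlapping hits are excluded — they are microsatellite
territory.  Pairs sharing a copy merge into classes.  The 100 bp rule is
applied as ≥ 100: published repeat tables list classes of exactly 100 bp
under a "longer than 100 bp" heading, so the inclusive reading is the one
consistent with the data.

Near-exact extension handles the situation of a long duplication whose
copies differ by a handful of mutations: exact cores whose copies lie
within 50 bp of each other fuse when a global alignment of the joint
spans stays within 1% edits (substitutions plus indel events, a
multi-base gap counting once), and each two-copy class then extends
outward while the extension itself stays near-exact (its own mismatches
bounded by the 1% rate plus one free edit, never amortised against a
long core — amortising would let a 14 kb repeat wander into random
flanking sequence).  Extensions shorter than 20 bp are discarded.

Microsatellites are maximal mismatch-free tandem runs of a 2–6 bp unit,
accepting di-nucleotide runs of ≥ 6 units and tri- through
hexa-nucleotide runs of ≥ 4 — the msatcommander-style thresholds used in
organelle surveys.  Units are reported in their lexicographically
minimal rotation; runs whose unit is a power of a shorter unit are
reported at the shortest unit; homopolymers are not microsatellites.

Repeat origin annotation names the feature a repeat was duplicated from:
a gene or intron qualifies when the overlap with a repeat copy reaches
80% of the shorter of feature and repeat.  That two-sided rule lets a
short repeat inside an intron report the intron, and a long repeat
containing complete genes report those genes, matching how published
repeat tables mix the two cases.  Introns are preferred over their host
genes as the more specific annotation.

## Gene-order comparison

Signed circular gene orders are compared on gene extremities.  Conserved
adjacencies are extremity pairs present in both orders; gene pairs
adjacent in both but with flipped relative orientation are reported
separately as reversed.  Conserved clusters are maximal runs of the first
order that appear as consecutive, co-oriented blocks (whole-block
reversal allowed — a circular chromosome has no absolute strand) in the
required number of genomes after restriction to the common gene set.

The rearrangement estimate charges: one deletion per maximal run of genes
private to one genome; one duplication per copy-number difference of a
shared gene; and, on the exemplar-reduced signed circular permutations,
the DCJ distance *n* − *c*, where *c* is the number of cycles of the
adjacency graph.  The published event vocabulary (deletion, duplication,
inversion, translocation) names no algorithm, so we adopt the standard
tractable model and label every estimate with its `method` string: each
elementary DCJ operation counts as one event, which prices an inversion
at 1 and a block translocation at 2 (excision plus reintegration through
a circular intermediate).  The test suite verifies the distance against a
breadth-first search over elementary DCJ operations on adjacency-set
states — exhaustively for all signed circular orders of up to 6 genes —
so implementation and oracle share one declared event model.  Two
consequences worth knowing: estimates are not comparable to hand counts
that price a translocation at 1, and with duplicated genes the exemplar
reduction (keep the copy whose neighbourhood best agrees with the other
genome, ties to the lowest coordinate) is a heuristic — the strict
"k inversions ⇒ estimate ≤ k" bound is guaranteed only on
duplicate-free orders, which is how the property is tested.

## The synthetic generator

`generate_genome()` emits an annotated circular genome plus a manifest of
everything planted.  Defaults mirror the scale of the largest archaic
vascular-plant chondrome: 413,530 bp, AT fraction 0.558, 66 unique genes
(37 protein / 3 rRNA / 26 tRNA) with a duplicated rRNA cluster and 11
duplicated tRNA copies, 32 cis-spliced group II introns, 69 pseudogene
fragments of 60–400 bp at 85–100% identity (70% retroposed), 8 planted
repeat classes plus the cluster duplication (one class near-exact with 3
edits, mirroring published footnote cases), 15 microsatellites (4 di, 9
tri, 2 tetra), 12 C-to-U + 5 U-to-C editing sites planted in one gene,
and 19 codon-reconstitution states (6 ACG starts, 4 internal stops, 9
editable stop codons).  Background sequence is i.i.d. at the configured
AT fraction; pseudogene fragments decay from their parent by independent
substitutions to a target identity.

Construction discipline keeps manifest and genome consistent: random
coding and background sequence is re-drawn wherever a threshold tandem
run would arise by chance, planted microsatellite runs get flanking
guard bases so they are maximal by construction, fragment decay caps any
exact run against the parent below the repeat-detection floor (otherwise
a near-identical 300 bp fragment would legitimately surface as a repeat
class), and a final scrub pass breaks tandem runs created at assembly
junctions, choosing substitutions that never create an in-frame stop
inside a protein gene.  Two planted structures intentionally overlap in
meaning: repeat classes carved from a real intron place one copy inside
the functional gene and one in a spacer, and that spacer copy *is* an
intron-retaining pseudogene fragment — the scan reports it as such, just
as published fragment inventories include intron fragments.  Fragments
of one parent can also share enough sequence to pair with each other at
or above the repeat floor when their random decay happens to coincide;
on a 413 kb genome this yields a couple of extra small repeat classes
beyond the planted count, which is why exact class-count equality is
asserted at the test scale (45–60 kb) and recovery-style checks are used
at full scale.

What the generator does not emulate: nucleotide composition structure
(no codon bias, no GC skew), rate heterogeneity or selection in fragment
decay, trans-splicing, transposons, and chimeric or foreign-DNA
insertions.  Passing on synthetic data therefore demonstrates
correctness of the detection logic under the stated noise model, not
robustness to every artefact of real organelle data — the GenBank reader
and all thresholds are, however, exactly what a real-accession run would
use.

## Problem sizes and determinism

The test suite generates genomes of 45–60 kb (full structure, reduced
gene count), checks the repeat and microsatellite engines against
brute-force oracles on sequences up to 5 kb over 100 seeded trials, and
verifies the rearrangement distance exhaustively to n = 6.  The
acceptance script regenerates the full 413.5 kb default genome and runs
every stage on it in a few minutes.  All randomness flows from explicit
seeds; the same seed reproduces a genome byte-for-byte, and the pipeline
itself is deterministic (re-running it on the same input reproduces
byte-identical reports).

## Known limitations

* The GenBank parser covers organelle-style records (LOCUS/FEATURES/
  ORIGIN, `join`/`complement` locations, `/gene`, `/pseudo`); it is not a
  general GenBank implementation.
* Origin classification is nearest-neighbour by p-distance, standing in
  for full phylogenetic placement; calls within the margin are
  `ambiguous` by design.
* The editing predictor is codon-wise and reference-based; it does not
  model editing-site context and will not reproduce the per-gene counts
  of trained predictors.
* Rearrangement estimates with duplicated genes rely on greedy exemplar
  selection and should be read as upper-bound heuristics there.
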