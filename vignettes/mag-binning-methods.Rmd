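---
title: "Bubble-chart binning, bin quality and comparative genomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bubble-chart binning, bin quality and comparative genomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magbinr)
library(dplyr)
```

magbinr makes a manual metagenome-binning workflow reproducible: contigs are
selected in G+C × coverage space, cleaned by composition, checked against a
universal single-copy marker set, scored, and the resulting genomes compared.
This vignette explains the underlying models and the design choices made
where the workflow is usually done by hand.

## The binning model

The workflow assumes a community of genomes that differ in two nearly
independent coordinates:

* **G+C content** — a genome-level property; contigs from one genome scatter
  tightly around their genome's value, with sampling spread shrinking as
  contig length grows.
* **Coverage (RPKM)** — proportional to the organism's relative abundance.
  RPKM (reads per kilobase per million mapped reads) removes both contig
  length and sequencing depth, so contigs of one genome share a common level.

A dominant organism therefore appears as a compact cloud in the bubble
chart, and an analyst circles it. `selection_region()` formalizes the circle
as a **closed axis-aligned rectangle** with an optional contig-length floor.
Rectangles, unlike free-hand polygons, are serializable in a config file,
trivially auditable, and monotone (a larger rectangle can only select a
superset), which the tests exploit. Boundary values are included, so a
contig exactly on `gc_max` belongs to the bin.

### Tetranucleotide refinement

Two genomes can overlap in (G+C, RPKM) yet differ in short-range sequence
composition. Each contig gets a tetranucleotide profile: 4-mer counts in a
sliding window (step 1, windows containing `N` skipped), with each 4-mer
merged with its reverse complement into one of 136 canonical classes.
Canonicalization matters because assembly strand is arbitrary — the profile
of a contig and its reverse complement are identical by construction, and a
property test asserts this on random sequences.

Refinement (`refine_by_tetra()`) iterates: compute the bin's
**length-weighted** mean profile (equivalent to the profile of the
concatenated bin sequence, so long contigs anchor the centroid), find the
member with the lowest Pearson correlation to it, and remove it if that
correlation falls below `min_correlation`. One removal per round keeps the
centroid stable; the loop stops when the bin is coherent, when `max_rounds`
(default 10) removals have been made, or when one contig remains. Contigs
with no valid window (all-zero profile) cannot be judged and are exempt. The
default threshold of 0.9 suits contigs of roughly ten kilobases and up —
at shorter lengths profile sampling noise alone pushes genuine members below
0.9, and the threshold should be lowered (it is exposed in the config).

### The single-copy marker rule

Bin contamination is diagnosed with a configurable universe of universal
single-copy genes (default 105): a correct single genome carries each marker
at most once. Markers enter as an annotation table (`contig_id`,
`marker_id`); detection itself (profile-HMM searches) is upstream of this
package. `dedup_markers()` enforces the end condition — *no marker on two
distinct contigs of a bin* — by repeatedly removing, among the carriers of a
duplicated marker, the contig least correlated with the bin centroid (ties:
the shorter contig, then the lexicographically larger id, so results are
deterministic). The rule deliberately operates **across** contigs: two copies
on one contig do not trigger removal (a single contig is a single piece of
one genome; tandem duplication is biology, not mis-binning) but are reported
as a warning.

## Bin quality metrics

* **Completeness** = 100 × distinct markers present / universe size.
  Presence/absence is counted, not copy number: copy-weighting would let a
  contaminating second copy *raise* completeness, which is backwards.
* **Predicted genome size** = assembled length ÷ completeness fraction, in
  Mb. This simple extrapolation reproduces the published per-bin values it
  was checked against to their printed 2 decimals (one published row is
  internally inconsistent with every other row's arithmetic and is treated
  as a rounding artifact of an unrounded completeness).
* **Relative abundance** = bin reads / total mapped reads × 100. The total
  is the metagenome-wide mapped-read count carried by the coverage table
  (`#total=` header line when the table is a subset).
* Bin G+C is length-weighted, i.e. the G+C of the concatenated bin sequence.
* The report flags bins above 70% completeness, the conventional reporting
  cutoff for reconstructed genomes in this workflow.

## Comparative genomics by bidirectional best hits

Orthologs between two proteomes are proxied by **bidirectional best hits**:
`(x, y)` is a pair iff `y` is `x`'s best hit in B and `x` is `y`'s best in A.
Scoring is Smith–Waterman local alignment with affine gaps (BLOSUM62, open
11, extend 1) via Biostrings; alternatively, standard 12-column BLASTP/
DIAMOND tables can be imported, thresholded at E ≤ 1e-5 — the conventional
cutoff for BBH surveys. Internally computed scores carry no E-value
(Karlin–Altschul calibration is out of scope), so internal mode thresholds
on raw score instead; the default floor of 60 sits far above the local-
alignment scores of unrelated proteins at typical lengths and far below
genuine ortholog scores. Ties in best-hit selection are broken by lower
E-value, then lexicographic subject id, making the pairing deterministic;
a test suite checks it against an exhaustive brute-force oracle across tens
of thousands of enumerated score matrices.

Because BBH assumes one representative per function per genome, redundant
within-genome duplicates are collapsed first (`dedup_paralogs()`):
single-linkage clusters at ≥ 90% local-alignment identity over the shorter
sequence, keeping the longest member. What counts as a "duplicate gene" is
an operationalization choice; the identity threshold is exposed.

For three genomes, each gene is assigned to the Venn region named by its own
genome plus every genome in which it has a BBH partner. Assignment is
**per gene from its own edges**, not by orthogroup connected components, so
a non-transitive BBH triangle cannot corrupt the partition: a gene with
partners in both other genomes sits in the triple region even if its two
partners are not mutually paired. The regions of interest in a
focal-vs-two-references comparison are the focal-only region (peculiar CDSs)
and the region shared by both references but missing from the focal genome
(lost functions).

## Neighbor-joining phylogeny

Distances are uncorrected p-distances by default: at saturation levels where
model correction matters, distance methods are the wrong tool anyway, and
the uncorrected distance never produces undefined values. An optional
Poisson correction `-ln(1 - p)` for amino acids is provided. Sites with a
gap, `X`, `?` (or `N` for nucleotides) in either sequence are excluded per
pair (pairwise deletion, the common default in desktop phylogenetics tools);
complete deletion is available. A pair with zero comparable sites is an
error naming the pair.

`nj_tree()` implements Saitou–Nei neighbor joining with the Studier–Keppler
Q-criterion. It is written in-package rather than delegated because the
contract requires deterministic tie-breaking (ties in Q join the
lexicographically smallest label pair) and clamping of negative branch
lengths to zero with a warning — conventions matching common desktop tools;
the independent `ape::nj()` implementation serves as a cross-check oracle in
the tests. NJ is exact on additive matrices, and the suite verifies exact
topology and branch-length recovery (within 1e-9) on random tree metrics
with 4–10 taxa, plus brute-force four-point-condition enumeration for
quartets.

Bootstrap (`nj_bootstrap()`) resamples alignment columns with replacement
under a fixed seed, rebuilds the tree per replicate, and counts recurrences
of each internal bipartition of the full-alignment tree. Supports of 50 or
below are computed and written, but flagged `shown = FALSE`, mirroring the
usual ">50 shown" display rule — filtering is a display decision, not a data
decision.

## The synthetic-community generator

The generator is the package's test bed. It emulates exactly the structure
the binning method assumes:

* **Genome sequences** come from randomly initialized order-3 Markov chains.
  Order 3 is the smallest order that produces genuine tetranucleotide-level
  structure. Per-context conditional G+C is jittered in logit space
  (`jitter_sd`, default 0.8) around the genome target — this is what gives
  each genome its own 4-mer signature; 0.8 yields within-genome centroid
  correlations around 0.94–0.97 for contigs of 10 kb and up, comparable to
  the compositional coherence of real genomes, while different seeds give
  clearly separated signatures. Realized G+C is calibrated to the target
  within about one percentage point by iterating a logit offset.
* **Contigs** have truncated-lognormal lengths (default median 20 kb,
  minimum 10 kb). These are the scales of well-assembled dominant organisms
  — published methylotroph bins average tens to hundreds of kb per contig —
  not the sub-kb tail of a whole-metagenome assembly.
* **Read counts** per contig are Poisson with expectation
  `total_reads × abundance × contig_length / genome_length`, so realized
  abundances fluctuate around the configured weights exactly as independent
  read assignment would produce.
* **Markers** are planted as table rows (one contig per marker per genome,
  length-weighted placement), not as sequence motifs — the table is the
  detection output, so the 105-gene logic is testable without HMMs.
* **Protein sets** contain core ortholog families copied into every genome
  with independent per-site substitutions, plus genome-specific accessory
  genes, giving a known Venn design.

Everything derives from one integer seed (per-genome sub-seeds are drawn
from it), so outputs are byte-identical across runs.

**What passing these tests does and does not show.** The generator omits
real-data complications on purpose: no sequencing error or chimeric contigs,
no strain mixtures, no repeat-induced coverage spikes, no conserved regions
shared between genomes, no marker mis-annotation, and contig composition is
stationary (real genomes carry horizontally transferred islands with alien
composition). Recovery of synthetic communities therefore validates the
*logic* — selection geometry, refinement convergence, the marker rule,
quality arithmetic, BBH/Venn bookkeeping — not binning performance on hard
real metagenomes, where manual binning of minor community members is known
to need caution.

## Test problem sizes

The acceptance-level tests run, by choice, at desk scale: a three-genome
community (G+C 45/55/63%, abundances 0.6/0.3/0.1, ~500 contigs, 200k reads)
for bin recovery; 50 small two-genome communities for the marker-rule
property; exhaustive BBH-oracle enumeration over all 2×2–3×3 score matrices
with scores in {1,2,3} plus seeded random matrices up to 6×6 and 100 random
20×20 matrices; 100 random additive matrices (4–10 taxa) for NJ exactness;
and 1,000 random sequences for strand invariance. Dataset-dependent
headline results of the original activated-sludge study (its 17 bins, its
specific abundances) require the deposited raw reads and are out of scope.

## Numerical conventions and degenerate inputs

* G+C excludes `N` from numerator and denominator; an all-`N` sequence is an
  error rather than a silent 0.
* Tetra profiles of sequences with no valid window are all-zero and flagged,
  never `NaN`.
* RPKM with zero total mapped reads is an error; zero mapped reads give
  RPKM 0 exactly.
* Newick output prints branch lengths to 6 decimals; bootstrap supports ride
  as internal node labels, so files round-trip through any standard parser.
* All tie-breaks (Q-criterion, best-hit selection, duplicate-marker
  resolution, paralog cluster representatives) are total orders, so every
  pipeline stage is deterministic given its inputs and seed.

## Known limitations

* Selection regions are rectangles; genuinely curved cluster boundaries need
  either a tighter rectangle plus refinement, or several rectangles.
* Internal alignment mode reports raw Smith–Waterman scores, not E-values;
  for genome-scale proteomes, import pre-computed BLAST/DIAMOND tables
  instead (the all-vs-all aligner is quadratic and meant for desk-scale
  sets).
* Completeness inherits the marker table's quality: missed or spurious
  marker annotations shift it directly.
* NJ with p-distances is a phenetic method; it is exact on additive inputs
  but makes no likelihood claims.
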