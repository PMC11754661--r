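---
title: "Long G4-rich enhancers: discovery, promoter G-triplet capacity, and Pore-C contact mining"
author: "lg4scape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Long G4-rich enhancers: discovery, promoter G-triplet capacity, and Pore-C contact mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lg4scape)
```

## The scientific problem

G-quadruplexes (G4s) are four-stranded DNA structures built from stacked
G-quartets; the minimal sequence considered G4-capable is four runs of at
least three guanines separated by short loops (GGGnGGGnGGGnGGG).  Beyond
such short motifs, the genome contains kilobase-scale loci that are densely
packed with G-triplets — long G4-rich loci, "LG4s", operationally defined
as regions with at least 80 GGG repeats per 1000 bp.  Many LG4s coincide
with annotated enhancers, and their target-gene promoters are themselves
G-triplet-rich, which has motivated a model in which an LG4 enhancer and a
promoter jointly contribute G-runs to *composite* quadruplexes, physically
tethering the two elements.  Single-molecule support for the required
spatial proximity comes from Pore-C: nanopore-sequenced proximity-ligation
concatemers in which restriction fragments that were close in the nucleus
appear on one read.

`lg4scape` implements the computational side of this programme as a
reusable, fully testable pipeline:

1. **g4scan** — G-run detection, minimal-G4 motif finding, windowed
   GGG-repeat density profiles, and LG4 calling.
2. **enrichment** — promoter G-triplet counting in upstream windows,
   length/composition-matched control loci, enhancer-overlap enrichment,
   chi-square triplet enrichment, and a neighborhood gene-fusion test.
3. **porec** — multi-mapping masking, seed-and-extend fragment alignment
   of concatemer reads, best-hit resolution, and LG4:promoter
   co-occurrence calling within single reads.
4. **synthetic data** — seeded genomes and Pore-C-like reads with planted,
   exactly known truth, so every stage is verifiable without downloads.

## Coordinate conventions

All user-facing coordinates are 1-based inclusive (Ensembl-style), so the
Chr5 LG4 at `Chr5:551935:556936` spans `556936 - 551935 + 1 = 5002` bp.
BED I/O converts to 0-based half-open at the file boundary (rtracklayer).

Upstream promoter offsets denote the half-open interval `[-far, -near)`
relative to the TSS.  This convention is fixed by the nested
deletion-construct spans of the EXOC3 promoter mapping series: the pairs
(2108, 1126), (1592, 1444) and (1592, 1557) must give 982, 148 and 35 bp,
and only `[-far, -near)` yields all three.

```{r}
upstream_window_length(c(2108, 1592, 1592), c(1126, 1444, 1557))
```

Upstream windows are resolved strand-aware by default (`[-far, -near)`
upstream of a minus-strand TSS lies at higher genome coordinates).  Whether
genome-wide promoter scans in the literature were strand-resolved is
usually not stated; `strand_resolved = FALSE` switches to plain
left-of-TSS windows.

## Counting G triplets

A G-run is a *maximal* stretch of >= 3 consecutive G on one strand
(minus-strand runs are plus-strand C-runs; `N` never matches, so a run
interrupted by N is two runs).  "GGG repeats" are counted by tiling each
maximal run into non-overlapping GGG units — a run of length L contributes
`floor(L/3)` — because a "repeat count" implies disjoint units: `GGGGGG`
is two stacked triplets, `GGGGG` only one.  The alternative reading
(number of runs >= 3) is available as `counting_mode = "runs"` everywhere
counts are produced, so both interpretations of published per-window
counts can be reproduced.

## LG4 calling

`call_lg4()` slides a 1000 bp window at 100 bp steps (both configurable),
marks windows whose per-strand density reaches the threshold (default 80
repeats/kb), merges overlapping/adjacent marked windows, trims each merged
region to the span of step-cells whose fine-scale density also clears the
threshold, and finally snaps the boundaries to the outermost contributing
G/C run.  The two-stage trim matters: a 1 kb window that only partially
overlaps a dense block can still clear 80/kb, so merged regions
over-extend into flanking background by up to
`window * (1 - threshold/block_density)` per side; the step-cell trim
restores boundary precision to about one step for blocks comfortably above
threshold, and the run-snap anchors the call to actual sequence rather
than the scan grid.  Calls shorter than `min_length` (default 1000 bp, the
kilobase scale that distinguishes LG4s from isolated motifs) are dropped.
The window/step/min-length defaults were chosen once so that multi-kb
exemplar loci are comfortably callable; the published 301-locus catalogue
came from a scan whose exact mechanics are not restated here, so no claim
is made of reproducing that catalogue locus-for-locus.

Lowering the threshold can only add marked windows and widen qualifying
spans, so calls are monotone in the threshold (tested as a property).

## Enrichment statistics

**Matched controls.** Control loci are drawn uniformly, matched to each
source locus in exact length and in GC within ±0.02 (configurable), and
rejected if they overlap any source locus or a previously placed control
of the same set; sampling is seeded.  On a compositionally uniform
background a 75%+ GC quadruplex block has no matchable territory, which is
faithful to the method's logic — composition matching presupposes
composition heterogeneity — so the synthetic generator can plant neutral
GC-shifted regions (`gc_regions`) that mimic isochores.

**Enhancer-overlap enrichment.** Comparing one real overlap count against
a handful of per-set control counts with a t-test is ill-posed (n = 1 in
one group), so the default contract compares per-locus 0/1 overlap
indicators of real loci against pooled control loci with a one-tailed
pooled-variance t-test (direction: real > control).  The literal
one-observation-versus-sets reading is retained behind `mode = "sets"` as
a Crawford–Howell single-case t.

**Chi-square triplet enrichment.** The 2x2 table is built on base-pair
occupancy — triplet bp = 3 x triplet count versus remaining window bp —
so groups with unequal total window length compare fairly; Pearson
chi-square, no continuity correction, df = 1 (a Yates option is
deliberately not applied by default, and any expected cell < 5 flags the
result).  A caveat stated here because it is easy to miss: occupancy moves
in 3-bp blocks, so on sequence-level data the occupancy cells are
over-dispersed relative to a per-bp multinomial by up to a factor of ~3,
making the test anti-conservative for near-null effects.  The package's
type-I calibration check therefore simulates from the test's own null
model (per-bp independent occupancy, binomial cells), which verifies the
kernel itself; conclusions drawn from occupancy chi-square on real
promoter groups should rely on effect sizes this large-sample test merely
confirms.

**Fusion neighborhoods.** Per-neighborhood counts of fusion pairs with
both partners inside the neighborhood, real versus control, two-tailed
Welch t-test.  No multiple-testing correction is applied by default.

## Pore-C mining

**Masking.** Any promoter substring longer than 100 bp that perfectly
matches two or more genomic locations (either strand) is replaced by N
before alignment; the rule is strictly "> 100 bp", so an exactly-100-bp
duplication survives.  Masking is implemented as 101-mer occurrence
counting (Biostrings `PDict`), since a duplicated stretch longer than
100 bp exists iff some 101-mer inside it occurs twice.

**Alignment.** Fragments of a concatemer read are placed by seed-and-
extend: exact 15-mers (the word size) seed per-(chromosome, strand)
diagonal clusters, which are extended by banded affine-gap local dynamic
programming with match +2, mismatch −3, gap open 5, gap extend 2.  The
read is then segmented greedily by score; equally scoring placements of
the same segment are counted (`n_equal_best`) and the tie is broken by
the smallest genomic coordinate, with the fragment flagged ambiguous.
Ranking by raw score stands in for ranking by e-value: at fixed scoring
parameters and database size the e-value is monotone decreasing in score,
so "lowest e-value" selects the same placement; the default score floor
is 100.  At a ligation junction a local alignment typically gains a few
net-positive bases of the neighbouring fragment, so segments may overlap
the read by a few bp; overlaps up to 30 bp are trimmed off the
lower-scoring segment (strand-aware, score adjusted) rather than treated
as conflicts, which keeps accepted segments strictly disjoint on the
read.  For repeat-dense fragments the seed cluster spans many spurious
off-register diagonals; the extension band is then re-centred on the
best-supported diagonal and capped (±40), which is ample for
substitution-dominated long reads.

**Contacts.** A contact is a read carrying one non-ambiguous fragment
overlapping an LG4 interval and a *different* fragment (disjoint read
span) overlapping a promoter window.  Ambiguous fragments are excluded by
default (`include_ambiguous = TRUE` re-admits them).  One pass — read
fragments to genome, then interval intersection — replaces the two-pass
promoters-to-reads-then-genome procedure; for contact calling the two are
equivalent, and the single pass is simpler to verify.  Low-complexity
filtering is deliberately absent (G-rich targets *are* low-complexity).

## The synthetic generator

`make_genome()` draws i.i.d. background at a configurable GC (default
0.40, giving ~5 GGG repeats/kb per strand, far below the 80/kb calling
threshold), then writes planted features over it:

* **LG4 blocks** — `n_units` copies of a unit such as `GGGT` (250
  repeats/kb).  With `jitter = TRUE` the non-G positions of each copy are
  randomised; the triplet count per block is unchanged, but the block
  becomes aperiodic and hence uniquely mappable.  This matters for read
  simulation: a perfect tandem repeat is self-similar at every unit
  offset, so fragments from it would be intrinsically ambiguous and no
  aligner could place them uniquely.  Real LG4s are G-dense but
  imperfectly periodic; jitter emulates that property.
* **Promoters** — the 5 kb upstream window is scrubbed of background
  G/C runs and receives exactly `planted_triplets` isolated GGG tracts
  (separated by non-G bases), so the plus-strand count is exact by
  construction under either counting mode and the minus-strand count is
  zero.
* **Duplications** — verbatim copies of a source interval at seeded
  random positions, used to exercise multi-mapping masking and
  tie-resolution.
* **GC regions** — background re-drawn at a different GC, providing
  matched-control territory.

`simulate_porec()` digests the genome at GATC (DpnII; the cut is placed
immediately 5' of each site, so fragments tile each chromosome exactly)
and assembles reads of 3–12 fragments (uniform; the real fragment-number
distribution is dataset-dependent, so this is a modeling choice, not a
measured value).  With the pair's contact probability a read receives one
LG4-overlapping and one promoter-overlapping fragment plus filler
fragments from the surrounding ±250 kb neighborhoods (insulated-
neighborhood locality without a polymer model); otherwise all fragments
come from one random neighborhood.  Filler fragments never overlap any
planted LG4 or promoter window, so the truth labels are exact and the
contact caller can be held to *exact* truth recovery at zero error.
Fragments are independently reverse-complemented with probability 0.5,
substitutions are injected per base (substitution-only; an indel-bearing
error model would invalidate the exact score arithmetic the tests rely
on and is not implemented), fragment order is shuffled, and everything is
seeded: identical spec + seed gives byte-identical output.

What the generator does *not* emulate: realistic nanopore error profiles
(indels dominate real nanopore error), chromatin-driven contact frequency
decay, restriction-site density variation, or genome-scale repeat
families.  Passing tests therefore demonstrate the correctness of the
pipeline's logic and arithmetic on data satisfying its assumptions — they
do not certify recall on real SRA Pore-C runs.

## Problem sizes and numerical choices

The packaged checks run at desk scale, chosen once as the smallest sizes
at which each property is decisively testable: 20 seeded 40 kb genomes
for LG4 recovery/specificity; a two-chromosome 700 kb demo genome with
two LG4s and six promoters; 500 reads for exact truth closure and 1000
reads for the contact-rate check (3 binomial standard errors around
p = 0.3); 1000 replicates for the chi-square type-I rate.  Genome-scale
claims (the 301-locus catalogue, genome-wide promoter means, the 74-fold
availability ratio) require hg38 plus external databases and are
represented by these property-based substitutes; `call_lg4()` on a real
genome FASTA is supported but not part of the test surface.

Tie-breaks and degenerate inputs are all deterministic: equal alignment
scores resolve to the smallest (chromosome, start); zero-variance t-test
inputs return flagged boundary p-values rather than NaN; a zero promoter
mean flags the availability ratio; chromosomes shorter than one window
produce a single scaled partial window.

## Known limitations

* The LG4 scan defaults are a faithful reading of the stated density
  criterion, not a reimplementation of the original catalogue scan.
* Occupancy chi-square is anti-conservative under triplet clustering (see
  above).
* The aligner reports raw scores, not Karlin–Altschul e-values; score
  ranking is equivalent for best-hit resolution but the absolute
  thresholds are not interchangeable with BLAST e-value cutoffs.
* Contact calling treats any same-read co-occurrence as one contact; no
  attempt is made to model ligation-order or multi-way contact topology.

## A worked run

```{r, eval = FALSE}
out <- run_demo(tempfile("lg4demo"), seed = 7)
out$calls            # two planted LG4s, called and trimmed to the blocks
out$contact_summary  # per-pair read support recovered from simulated reads
verify_paper()       # curated-fixture quantities, recomputed
```
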