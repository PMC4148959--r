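---
title: "Discovering common non-reference insertions from pooled one-end-anchored reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering common non-reference insertions from pooled one-end-anchored reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micseqr)
library(data.table)
```

## The problem

Reference genome assemblies are consensus constructs: sequences carried by a
substantial fraction of a population can be entirely absent from them. An
individual who carries such a "missing common sequence" (micSeq) produces
paired-end reads that betray it in a characteristic way. A fragment that
straddles the insertion boundary yields one mate that aligns to the
reference (the *anchor*) and one mate, drawn from the novel sequence, that
aligns nowhere (the *orphan*) — a one-end-anchored (OEA) pair. A fragment
wholly inside a long insertion yields a pair in which neither mate maps (a
*full orphan*).

At the shallow coverage typical of population-scale sequencing (~4x per
individual), no single genome can be assembled. The insight this package
implements is that the *pooled* orphan reads of many individuals can: a
sequence present in many genomes accumulates pooled coverage proportional
to its carrier count, so assembling the pooled orphans under a stringent
k-mer coverage cutoff recovers exactly the common insertions and discards
individual-specific ones. The anchors, which were recorded alongside their
orphans, then localize each assembled sequence on the reference, expose
false assemblies, and genotype every individual.

## Pipeline stages and their parameters

**Quality trimming.** Reads are scanned 5'→3' in sliding windows of 4
positions; at the first window whose mean Phred quality falls below 25 the
read is truncated at that window's first base, and a read trimmed below
20 nt drops its whole pair. Trailing windows shorter than 4 are averaged
over their actual length — the read end then contributes windows of
decreasing size, which is the simplest reading of sliding-window semantics
at the boundary; leading-end trimming and adapter clipping are out of scope
(simulated reads carry no adapters). Because the truncation point is a pure
function of the quality string, the vectorised trimmer memoizes it per
distinct quality string.

**OEA classification and pooling.** "Uniquely mapped" is operationalized as
MAPQ ≥ 20 (configurable); a pair with exactly one uniquely mapped mate and
one unmapped mate is OEA. A pair whose only mapped mate falls below the
MAPQ threshold is demoted to full orphan; a pair with one unique and one
mapped-but-ambiguous mate is counted with the both-mapped discordants,
since both mates did align. Concordance requires FR orientation within
mean ± 4 sd of the insert size (estimated from the data when not supplied).
Orphans are pooled across all samples and binned by their anchor's
chromosome; orphans anchored to different chromosomes are never
co-assembled. Each orphan is oriented before assembly: the mate of a
forward-strand anchor is reverse-complemented, so all orphans present the
inserted sequence in its forward sense relative to the reference. Full
orphans are recorded but not assembled — they would extend reach into long
insertions, at the cost of losing the anchor-based false-positive control
that drives the filtering stages.

**Multi-k de Bruijn assembly.** Pooled orphans are assembled at every k in
19, 23, ..., 59 (odd k avoids palindromic k-mer ambiguity). k-mers are
counted double-stranded (a k-mer and its reverse complement are one edge).
Unbranched paths are compressed into unitigs; short low-multiplicity tips
(< 2k nt, mean multiplicity < cutoff/4) are clipped; edges below the
coverage cutoff — 50x by default, the commonness dial of the whole method —
are deleted; and contigs of ≥ 100 nt whose mean k-mer multiplicity reaches
the cutoff are reported. Traversal and tie-breaks are lexicographic, so
assembly is a pure function of the read multiset. The cutoff is interpreted
as *k-mer* coverage (the knob is exposed); note that k-mer coverage is
lower than base coverage by the factor (L−k+1)/L for read length L, which
matters when reasoning about which insertions are recoverable. Because the
double-stranded graph forgets strand, each contig is re-oriented afterwards
to the majority orientation of its supporting reads. Bubble popping and
paired-end scaffolding are deliberately not replicated: at the coverage
cutoffs used here the graph is essentially branch-free after thresholding,
and the cutoff serves as a population-frequency filter, not a
repeat-resolution device.

**Similarity-graph merging.** The per-k assemblies are redundant. Contigs
(per anchor chromosome) become nodes of a similarity graph with an edge
wherever the best local alignment between two contigs (either strand) has
e-value below 1e-10; each connected component — including singletons
assembled at only one k — contributes its longest member as one candidate
(ties: higher mean coverage, then lexicographically smaller sequence).
E-values follow the Karlin–Altschul form `E = K·m·n·exp(−λS)` with λ solved
numerically from the score moment equation under uniform base composition
(match +1, mismatch −2 gives λ ≈ 1.33) and K fixed at 0.1. K is a
calibration constant: near-identical 100+ nt contigs sit more than a
hundred orders of magnitude below the edge threshold while unrelated
contigs sit above it, so its exact value cannot change any edge decision.

**Filtering.** Candidates pass an order-fixed chain, each verdict appended
to an audit trail:

1. *Known/low-complexity*: a candidate alignable to the reference at
   ≥ 95% identity over ≥ 90% of its length is a known sequence; a
   candidate more than 80% masked by a DUST-style triplet score (64-nt
   windows, threshold 2.0) is low-complexity. Both thresholds are package
   choices — strict enough to retain diverged homologs — exposed in
   `filter_config()`.
2. *Anchor clustering*: a true insertion concentrates its anchors at one
   locus. Among 4-kb windows anchored at each anchor position, the leftmost
   window holding the maximum count is recorded; the candidate fails if
   under 50% of its anchors (distinct pairs) fall inside. Anchors on
   non-modal chromosomes count only in the denominator.
3. *Local reference*: the reference spanning the anchor cluster ± 1 kb is
   extracted (clipped at chromosome ends); candidates alignable to it are
   removed.
4. *Contaminant*: candidates alignable to any supplied contaminant
   sequence (e.g. viral genomes from transformed cell lines) are removed;
   with no contaminant set the step records "skipped".

Regions where several surviving candidates have overlapping anchor
clusters are reassembled from the region's orphans at a relaxed 20x
cutoff, keeping the single longest contig — fragments of one longer
insertion whose mid-section dipped below 50x are thereby joined.

**Flank trimming.** An orphan read can carry up to read-length−6 nt of
reference sequence from the boundary, so assembled candidates extend past
the novel insertion into its flanks. Each end of a candidate is locally
aligned to the anchor-cluster reference segment; an end-anchored match at
≥ 95% identity is trimmed off, leaving the novel core. Cores shorter than
the 100-nt minimum are discarded. Without this step every call would be
diluted by flanking reference sequence in proportion to read length.

**Breakpoints, carriers, frequencies.** Forward-strand anchors flank the
insertion on the left, reverse-strand anchors on the right, so the
breakpoint is estimated as the midpoint between the rightmost forward-
anchor end and the leftmost reverse-anchor start when the two reconcile
within 500 nt; otherwise the anchor-cluster span is reported as an interval
(~1 kb effective resolution, matching what anchor geometry can deliver).
Carriers are called post hoc by re-mapping each sample's orphan reads onto
the final sequence (exact 15-mer seed, ungapped extension at ≥ 95%
identity): a sample carrying ≥ 3 mapping orphans is a carrier, and calls
with overall carrier fraction below 1% are dropped. Re-mapping, rather than
tracking which reads the assembler consumed, keeps frequencies
recomputable from any read set after the fact. Gene context takes the most
specific overlapping annotation feature (exon > UTR > intron), then a 5-kb
flank class, then intergenic. Evidence read sets (RNA-seq, ChIP-seq) are
counted with the same mapper; a dataset exceeding 100 reads on a call flags
it as expressed/bound, and control datasets are reported side by side.

**Population stratification.** Printed per-population frequencies are
converted back to integer allele counts (`round(freq × n × ploidy)`, half
up; diploid by default, with ploidy 1 available if values are read as
carrier fractions) and the African counts are tested against the pooled
non-African counts with a two-sided Fisher's exact test. No
multiple-testing correction is applied, matching the raw 5%-level
convention of the validation analysis. The packaged 15-row validation
table reproduces the published pattern: 12 African-maximum rows, 9
significant, and the strongest signal (micSeq30) at p ≈ 1.2e−7.

## What the simulator emulates — and what it does not

`simulate_cohort()` builds a uniform-random reference, plants
non-reference insertions (random sequences, rejected if DUST-masked or
alignable to the reference, so novelty holds by construction) at
configured allele frequencies, draws binomial genotypes per diploid
individual, and generates FR read pairs with normal insert sizes, i.i.d.
substitution errors and constant qualities matching the error rate. Its
*ideal aligner* maps a read iff ≥ 95% of its bases derive from reference
sequence, at the read's reference projection with MAPQ 60. This replaces a
real aligner deliberately: tests then isolate the pipeline's own
computation from aligner idiosyncrasies, and every read's OEA/full-orphan
status follows from fragment geometry exactly.

Real data differ in ways the simulator does not model: indel and
context-dependent errors, quality decay along the read, GC and coverage
bias, duplicate fragments, soft-clipped boundary alignments, repetitive
reference context, and diverged (rather than absent) insertion homologs.
Passing tests therefore certify the pipeline's logic under clean OEA
geometry, not robustness to aligner soft-clipping or repeat-induced
mismapping.

A consequence of assembling only OEA orphans is worth stating explicitly:
near an insertion boundary roughly half the fragments covering a position
have their second read also inside the insertion, making them full
orphans. Pooled OEA orphan coverage near boundaries is therefore about 1x
per carrier haplotype (not the 2x of total haplotype coverage), and for
insertions much longer than the insert size the interior receives no OEA
coverage at all — calls for long insertions are boundary cores, which is
also the published behaviour (assembled sequences are parts of longer
insertions). With 200 individuals at 4x, an allele frequency around 0.15
is the practical floor for clearing the 50x cutoff; the recall suite
samples frequencies in {0.2, 0.3, 0.5}.

## Test and acceptance problem sizes

The package's own test harness runs at desk scale, chosen to exercise every
stage in minutes on one core: end-to-end recall uses 10 seeded cohorts of
200 individuals (70/70/60 across three populations) on a 50-kb chromosome
with three insertions each (150–800 nt); precision uses 20 insertion-free
cohorts of 50 individuals; the carrier-frequency check uses 20 cohorts at
a true carrier rate of 0.30. Property suites check the trimmer, the
anchor-cluster window, local alignment scores and the Fisher test against
independent brute-force oracles, and the assembler against exact
reconstruction of known sources. `scripts/acceptance.R` re-runs the
stratification analysis and a 4-seed recovery experiment from scratch and
writes the resulting numbers as JSON.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; SAM (1-based) and BED
  (0-based) are converted only at file boundaries.
* All tie-breaks are lexicographic (assembly traversal, representative
  selection, window choice is leftmost-maximal), so every stage is
  deterministic and input-order independent; the only randomness anywhere
  is the simulator's seeded RNG.
* Empty inputs degrade cleanly: an empty read set assembles to nothing, a
  zero-insertion cohort yields zero calls, degenerate Fisher margins give
  p = 1, and a cluster at a chromosome edge clips its padding.
* `rescue_assemble` never returns a contig shorter than the best strict-
  cutoff candidate (the region keeps its longest member if rescue fails).

## Known limitations

* The breakpoint's strand-reconciliation rule and its 500-nt tolerance are
  this package's construction; anchor geometry supports ~1 kb resolution
  and no better claim is made.
* Carrier calling at 4x with the ≥ 3-read rule systematically undercalls
  carriers (a binomial detection effect); estimated frequencies are biased
  low by up to ~0.2 at high carrier rates. The bias shrinks with coverage
  and with `min_reads_carrier`, which is exposed.
* The contaminant screen is only as good as the supplied contaminant set;
  nucleotide-database-scale screening is out of scope.
* Both-mapped discordant pairs (CNV/inversion signals) and split-read
  evidence are recorded but not interpreted.
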