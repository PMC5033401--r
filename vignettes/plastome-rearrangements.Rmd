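---
title: "Models and methods: plastome rearrangement analysis with plastinv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: plastome rearrangement analysis with plastinv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastinv)
```

## The problem

Most angiosperm plastid genomes (plastomes) are circular molecules of
roughly 120–160 kbp with a conserved quadripartite layout: a large and a
small single-copy region (LSC, SSC) separated by two perfect inverted
repeats (IRa, IRb). Against this conserved backdrop, a few lineages — the
graminid Poales prominently among them — have accumulated large (hundreds
of bases to tens of kilobases) inversions in the single-copy regions.
Reconstructing *which series of inversions* turned one observed
arrangement into another, and certifying that a proposed series is the
most parsimonious, is the core task this package addresses.

`plastinv` models a plastome region as a **signed arrangement**: an
ordered list of uniquely labelled colinear blocks, each with an
orientation sign. An inversion excises a contiguous run of blocks and
reinserts it in place, reverse-complemented — at block level it reverses
the interval and negates every sign. Regions are modelled as *linear*
segments between the IR boundaries, matching how per-region rearrangement
diagrams are drawn; whole-circle arrangements are deliberately not
modelled.

## The stochastic search (DIMSUM) and its exact oracle

`dimsum()` implements a Monte Carlo search over inversion series:
each of `replicates` independent walks starts at the source arrangement
and repeatedly applies an event drawn uniformly at random from all
`n(n+1)/2` contiguous block intervals — single-block flips and the full
segment included, since nothing in the biology privileges any interval —
checking for equality with the target after every step and stopping at
the first hit or after `max_steps` events (default 100, read as a
per-walk cap with early stopping). The event prefix up to the hit is the
recorded solution; the endpoint is also tested before the first event,
so a source that already equals the target yields the empty scenario.
Solutions are deduplicated by exact event sequence, while
`hits_by_length` counts replicate hits before deduplication, preserving
both views of "all solutions".

Because a stochastic minimum is only an upper bound, `exact_min_distance()`
provides the certificate: breadth-first search over the full signed
arrangement space (2^n · n! states, every inversion being its own inverse
making the state graph undirected). `enumerate_minimal_scenarios()`
extends the BFS with distance-decreasing backtracking to list *every*
shortest series in a deterministic lexicographic order, and
`certify_parsimony()` stamps a search result with the exact minimum. The
BFS is capped at 8 blocks (≈10.3 million states) by default; beyond that
the stochastic search is the intended tool. At the block counts that
arise in plastome work (2–4), the oracle answers in milliseconds. A
Hannenhalli–Pevzner polynomial-time distance was deliberately not
implemented: BFS is exact, simpler to audit, and more than fast enough at
this scale.

Two further diagnostics: `breakpoint_count()` computes signed breakpoints
(with fixed terminals framing the segment), whose half, rounded up,
classically lower-bounds the reversal distance; and the search/oracle pair
supports **flip equivalence**, under which an arrangement and its
whole-segment reverse complement are one state. This mode encodes the
biology of the SSC: between its flanking IRs the region occurs in
equimolar populations of both orientations, so its absolute orientation
carries no signal. Flip equivalence is off by default — the two-event SSC
reading is primary, the one-event reading its explicit alternative:

```{r ssc}
fx <- plastome_fixtures()
exact_min_distance(fx$ssc_pojo$source, fx$ssc_pojo$target)
exact_min_distance(fx$ssc_pojo$source, fx$ssc_pojo$target,
                   flip_equivalence = TRUE)
```

### Randomness and reproducibility

One seeded generator drives a whole `dimsum()` run: at each step one
proposal is drawn for every replicate in index order, whether or not that
replicate already hit its endpoint. This fixed step-major consumption
order makes results bit-identical for a given seed, independent of how
many replicates finish early, and lets the simulation run fully
vectorised across replicates (a 50,000-replicate run on a three-block
instance takes well under a second). The package-wide convention is that
*every* stochastic function takes an explicit integer seed and is a pure
function of (parameters, seed).

### Worked instances

The `plastome_fixtures()` block configurations encode the graminid-clade
rearrangements in the frame of the reference gene order (the
*Typha*/*Anomochloa* frames):

* `lsc_typha_anomochloa`: (+D-LSC3, +D-LSC1, +D-LSC2) →
  (+D-LSC2, −D-LSC3, −D-LSC1), i.e. the signed permutation (+3, −1, −2);
  exact minimum 2.
* `lsc_anomochloa_joinvillea` and `..._mirror`: the two-block Ja-LSC1/2
  exchange in its two mirror readings, (−2, +1) and (+2, −1). Published
  descriptions of this outcome differ on which block ends up inverted;
  the two readings are mirror-equivalent two-block outcomes, so both are
  shipped as named fixtures rather than guessing — deciding between them
  would need the deposited sequence itself. Both have exact minimum 2.
* `ssc_pojo`: the PoJo-SSC1/2 exchange, (−2, +1): minimum 2 strict,
  1 under flip equivalence.

## Deriving blocks from gene orders

The sequence-level step that normally precedes rearrangement analysis —
locally colinear block (LCB) detection with an aligner such as Mauve —
is replaced at desk scale by a gene-anchor surrogate, `collinear_blocks()`.
Plastome block boundaries fall at genes in practice, so shared
single-copy gene symbols serve as anchors: after `restrict_to_shared()`
drops genes not present exactly once in each order (IR-borne duplicates,
ambiguous symbols), the shared genes are partitioned into maximal runs
consecutive in both orders with a consistent joint orientation (same
order and strands, or exactly reversed order with all strands flipped).
Blocks are labelled `B1..Bk` in source order so the source arrangement is
the identity frame; a reversed singleton takes the sign of its strand
comparison. How an alignment-based LCB detector would merge or split any
particular pair of regions is not modelled; the surrogate is asserted
only to reproduce block-level arrangements whose boundaries lie at gene
boundaries.

## Quadripartite structure detection

`find_inverted_repeat()` locates the IRs from sequence alone: the longest
pair of disjoint, *exactly* reverse-complementary segments of at least
`min_ir_length` bp (default 1000 — comfortably below real plastome IRs at
~10–30 kbp, far above chance matches) on the circle, maximally extended
while exact complementarity holds. Exactness is a modelling choice, not a
shortcut: plastome IRs are perfect repeats, and `N` bases never match.
Implementation: exact k-mer seeds (k = min(20, `min_ir_length`); base-4
codes of up to 4^20 are exact in doubles, so seeding is collision-free)
between the circular sequence and its reverse complement chain into
maximal matches along diagonals, which avoids any per-base extension
loop; a 150 kbp circle is mapped in well under a second. Ties in repeat
length break toward the candidate with the longest larger single-copy
arc, then the smallest start coordinate, making output deterministic.
The larger arc is the LSC, and IRa is the copy immediately following it
in the forward direction. Coordinates are 1-based inclusive (GenBank
convention) with wrapped intervals for regions crossing the origin;
`quadripartite_bed()` performs the explicit conversion to 0-based
half-open BED rows.

`region_stats()` reports per-region lengths (which must sum to the
total), AT composition to one decimal (N in the denominator only), and
feature counts per region. Counts are reported both raw and
IR-deduplicated because conventions differ on whether IR-borne gene
copies count twice; the package asserts neither. `intron_count()` is
(parts − 1) of a gene's CDS/exon structure, preferring a CDS row over a
bare gene row and the first copy by coordinate when the name is
IR-duplicated.

## The synthetic-data generator

`synth_plastome()` builds circles laid out LSC + IRa + SSC + IRb with IRb
the exact reverse complement of IRa, mirrored features included. Its
default dimensions are those of a typical graminid-clade plastome —
LSC 85,526 bp, SSC 12,907 bp, IRs 25,447 bp each, 149,327 bp in total —
so structure detection is exercised at realistic scale. Sequence is
i.i.d. uniform over A/C/G/T (AT 50%) unless `at_fraction` is set; genes
are evenly spaced, never overlap, and never straddle region boundaries,
so per-region gene orders round-trip exactly. One non-obvious numerical
detail: if a single-copy region's first base complemented its last, the
exact repeat match would extend past the planted boundary by chance
(about a quarter of seeds), so generated single-copy junctions are
*sealed* — the offending first base is replaced by the region's last base,
which is never self-complementary. That makes planted-boundary recovery
exact rather than merely usual.

With `k_events > 0` the generator also emits a sibling record whose LSC
was cut into `n_blocks` contiguous gene blocks at intergenic midpoints
and hit by a known random series of block inversions, together with the
full ground truth (event list, block membership, source and target
arrangements). Every synthetic artifact carries enough truth to score
the detector, the block finder and the search without any external data.

What the generator does *not* emulate: substitution noise, indels,
pseudogene decay, duplicated or boundary-straddling genes, imperfect IRs.
Tests passing on synthetic data therefore demonstrate algorithmic
correctness under the stated model, not robustness to annotation noise in
real records — real-data runs go through the same `read_plastome()` path
but should be sanity-checked against their annotation.

## Problem sizes used in the shipped checks

The package's own verification suite runs the worked instances with
10,000-replicate searches, certifies stochastic/exact agreement
exhaustively over *all* signed arrangements of up to three blocks
(2 + 8 + 48 relative instances, which cover all ordered pairs by
relabeling invariance — `dimsum()` provably depends only on the relative
signed permutation) at 50,000 replicates across 20 seeds, and checks
structure recovery on a full 149 kbp synthetic circle. Replicate counts
are chosen so the chance of a walk missing a shortest series is
negligible: with n ≤ 3 the worst-case distance is 3 and a single walk
follows a shortest path in its first d steps with probability at least
6^−3, so 50,000 walks miss with probability below 10^−90. Published
certification runs at 1,000,000 replicates are reproduced in kind at
these reduced counts; the CLI default is 10,000 with the cap and
proposal distribution unchanged.

## Known limitations

* The oracle's BFS is memory-bound above 8 blocks; larger instances get
  only stochastic upper bounds.
* Translocations, transpositions and duplications are out of scope; an
  arrangement pair explained more parsimoniously by such events will
  still be reported purely in inversions.
* IR detection requires perfect repeats; genuinely degraded or
  mismatch-bearing IRs raise the no-IR error by design.
* The gene-anchor block finder needs shared single-copy anchors; gene
  orders with no usable anchors are rejected rather than guessed at.
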