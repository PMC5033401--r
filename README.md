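# plastinv — plastome rearrangement analysis by inversion scenario search

Plastid genomes (plastomes) are circular molecules with a conserved
quadripartite layout — a large and a small single-copy region (LSC, SSC)
separated by two perfect inverted repeats (IRa, IRb) — but some lineages,
notably the graminid Poales, carry large kilobase-scale inversions in
the single-copy regions. Given two arrangements of the same set of
locally colinear blocks, `plastinv` answers the questions a plastome
molecular evolutionist asks: *what series of inversions connects them,
how short can that series be, and is a proposed series certifiably the
most parsimonious?*

A region is a **signed arrangement** — an ordered list of labelled
blocks, each with an orientation sign; an inversion reverses a
contiguous block interval and negates its signs. Two complementary
engines operate on this model:

* **DIMSUM** (`dimsum()`), a seeded Monte Carlo search: many independent
  random walks apply uniformly random inversion events (at most
  `max_steps = 100` per walk) and record every event series that reaches
  the target, with per-length hit counts.
* An **exact oracle** (`exact_min_distance()`,
  `enumerate_minimal_scenarios()`): breadth-first search over the full
  signed-permutation space (2^n · n! states) returns the true minimal
  number of inversions and *all* shortest scenarios, certifying the
  stochastic result (`certify_parsimony()`).

Both support **flip equivalence** — treating an arrangement and its
whole-segment reverse complement as one state — which encodes the fact
that the SSC's absolute orientation between its flanking IRs is
biologically indeterminate. `breakpoint_count()` supplies the classical
lower bound d ≥ ⌈breakpoints/2⌉.

Around the core sit: `collinear_blocks()` (shared-block detection from
two annotated gene orders, anchored on single-copy shared genes),
`find_inverted_repeat()` / `region_stats()` (quadripartite structure
detection on raw circular sequence, with region lengths, AT% and
feature counts), gene-order extraction and intron counting from
FASTA/GenBank/TSV input, and a fully seeded synthetic-data generator
(`synth_plastome()`, `random_arrangement()`, `plant_inversions()`) that
emits ground truth with every artifact.

## Worked example

The three-block LSC instance: the *Typha latifolia* frame
(+D-LSC3, +D-LSC1, +D-LSC2) against the *Anomochloa marantoidea*
arrangement (+D-LSC2, −D-LSC3, −D-LSC1):

```r
library(plastinv)
fx <- plastome_fixtures()
res <- dimsum(fx$lsc_typha_anomochloa$source, fx$lsc_typha_anomochloa$target,
              replicates = 10000, seed = 1)
certify_parsimony(res)
#> DIMSUM search: 10000 replicates, max 100 steps, seed 1
#>   shortest series found: 2 inversion(s)
#>   replicate hits by length: 2:255  4:188  5:151  6:152  7:170  ...
#>   distinct solutions recorded: 7721
#>   certified exact minimum: 2
```

255 of 10,000 random walks found a two-event series, and the BFS oracle
certifies that two inversions is the true minimum — no shorter series
exists. The unique minimal scenario:

```r
enumerate_minimal_scenarios(fx$lsc_typha_anomochloa$source,
                            fx$lsc_typha_anomochloa$target)
#> [[1]]
#>   start end
#> 1     2   3
#> 2     1   2
```

First invert blocks 2–3 (D-LSC1 + D-LSC2, giving +D-LSC3 −D-LSC2
−D-LSC1), then blocks 1–2 — exactly the two documented large inversions.
For the SSC instance, `exact_min_distance()` returns 2 strictly and 1
under `flip_equivalence = TRUE`, reproducing both the two-event series
and its one-inversion alternative reading.

A shell interface wraps the same functions
(`exec/plastinv structure|blocks|distance|dimsum|simulate`), writing
JSON/TSV results with full configuration metadata; runs are offline and
byte-reproducible from their seed.

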