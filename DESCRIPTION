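Package: plastinv
Title: Plastome Rearrangement Analysis by Inversion Scenario Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying large-scale inversions in plastid genomes.
    Plastome regions are modelled as signed arrangements of locally colinear
    blocks; a seeded Monte Carlo search (DIMSUM) discovers series of
    inversions transforming one arrangement into another, and an exact
    breadth-first oracle certifies minimality and enumerates all most
    parsimonious scenarios, optionally treating an arrangement and its
    whole-segment reverse complement as equivalent (the single-copy-region
    orientation ambiguity). Companion modules derive shared blocks from
    annotated gene orders, detect the quadripartite LSC/SSC/inverted-repeat
    structure of circular plastomes with region statistics and per-region
    gene orders, and generate seeded synthetic arrangements, planted
    inversion histories and plastome-like records for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
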