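Package: phylomarkr
Title: Selection of Minimal Phylogenetic Marker Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to identify a minimal set of phylogenetic marker genes
    from collections of widespread single-copy gene alignments. Gene trees
    are ranked by their topological distance (Robinson-Foulds, normalized
    RF, or nodal distance) to a reference phylogeny built from the
    concatenation of all genes; an initial marker set is grown by
    progressive concatenation of top-ranked genes and then minimized by
    randomized and exhaustive subset search; selected sets are validated on
    held-out species by one-species-at-a-time placement and by
    cross-validation on an independent species set. Includes single-copy
    ortholog selection from BLAST tabular hit tables, built-in
    neighbor-joining tree inference with an external-engine hook,
    internode/tree certainty scores, and a sequence-evolution simulator
    that generates benchmarks with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    withr,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
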