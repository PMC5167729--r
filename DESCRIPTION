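Package: taxaudit
Title: Genome-Based Taxonomy Auditing with BLAST Distance Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing prokaryotic taxonomy against genome-scale
    evidence. Computes Genome BLAST Distance Phylogeny (GBDP) intergenomic
    distances from tabular local-alignment hits using greedy-with-trimming
    paralog correction and the coverage-robust d5 formula, builds
    neighbour-joining trees with pseudo-bootstrap support, classifies taxa
    as monophyletic, paraphyletic or polyphyletic with signed branch
    support, audits published genomic G+C content values against
    genome-derived values under the 1 percent rule, and tests whether
    genome-derived G+C values fit a phylogeny better than published ones
    via Farris-interval parsimony of a continuous character. Includes a
    seeded synthetic-data generator (Yule trees, Brownian trait evolution,
    genomes, draft subsamples, tree-consistent hit tables) so every stage
    can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.6),
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
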