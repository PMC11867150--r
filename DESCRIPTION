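Package: phylodag
Title: Parsimony History DAGs for Abundance-Aware B-Cell Lineage Inference
Version: 0.1.0
Authors@R:
    person("phylodag", "developers", email = "phylodag@example.org",
           role = c("aut", "cre"))
Description: Tools for storing, extending and ranking collections of
    maximum-parsimony phylogenetic histories with inferred ancestral
    sequences, using a history subsplit DAG (sDAG).  The sDAG stores shared
    substructure of many histories once and expresses every recombination of
    stored substructures, so completing and trimming it typically yields far
    more maximum-parsimony histories than were used to build it.  Histories
    are ranked by edge-decomposable criteria computed by dynamic programming
    on the DAG: a genotype-abundance branching-process likelihood, a Poisson
    5-mer context (somatic hypermutation) likelihood, and parsimony, combined
    lexicographically or as linear combinations.  Includes a germinal-centre
    B-cell affinity-maturation simulator with context-sensitive mutation for
    validation, and the MRCA sequence-distance metric for comparing inferred
    histories against true simulated genealogies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
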