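Package: paleosynteny
Title: Ancestral Karyotype Reconstruction from Gene-Order Synteny
Version: 0.1.0
Authors@R: person("URGI", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs ancestral plant karyotypes (conserved ancestral
    regions, or protochromosomes) from all-vs-all protein BLAST results and
    gene-position tables, using the four-step CIP/CALP method: conserved-gene
    detection by cumulative identity and alignment-length percentages,
    reduction to one-to-one (or 1-to-n under whole-genome duplication)
    ortholog relationships with tandem-duplicate collapse, chaining of
    ortholog anchors into synteny blocks, and merging of blocks into
    conserved ancestral regions with core/dispensable protogene
    classification and least/most-fractionated subgenome labelling. Includes
    a ground-truthed genome-evolution simulator (inversions, fusions,
    fissions, translocations, deletions, tandem duplications, whole-genome
    duplication with biased fractionation), readers and writers for the
    tabular exchange formats involved, dataset-consistency validation, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    ape,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
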