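Package: cladelim
Title: Delineation of Cryptic Genetic Lineages from Codominant Markers and
    Mitochondrial Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for delineating cryptic genetic lineages from classical
    codominant multi-locus data (allozymes, microsatellites scored as
    alleles) and aligned mitochondrial sequences.  Implements stepwise
    principal coordinates analysis of individual genotypes with an explicit
    cluster-gap rule, diagnosability via fixed allelic differences with a
    shared-allele tolerance, allele-frequency differentials, Nei's unbiased
    genetic distance, neighbour-joining trees, and p-distance summaries
    among and within clades under pairwise deletion.  Includes a synthetic
    genotype and sequence generator with known lineage structure so the
    whole pipeline can be exercised against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    seqinr,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
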