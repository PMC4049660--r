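Package: pooltag
Title: Pooled Cosmid Clone Sequencing: Simulation, Assembly and End-Tag Retrieval
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for evaluating pooled sequencing of large-insert cosmid
    clones from functional metagenomic libraries. Simulates a clone pool with
    full truth tracking (circular cosmids, Sanger end-tags with failures,
    paired-end reads with substitution errors and host genomic contamination),
    screens vector-derived reads at a strict 100 percent identity criterion,
    assembles the pool with a canonical k-mer de Bruijn unitig assembler,
    retrieves per-clone contigs by querying the pool with Sanger end-tags
    through a seed-and-extend local aligner, classifies retrieval outcomes
    into clone types, and scores results with identity, retrieved and actual
    coverage, pairwise clone similarity, contamination and read-depth metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, Assembly, Metagenomics, Software
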