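Package: metastrain
Title: Species, Gene-Content and Strain-Level Profiling of Shotgun
    Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated, reference-based pipeline for strain-level
    analysis of shotgun metagenomes. Delineates bacterial species by
    average-linkage clustering of genomes on averaged universal
    marker-gene distances, estimates per-sample species coverage and
    relative abundance from reads recruited to universal single-copy
    gene families, quantifies pan-genome gene copy number and
    presence-absence, calls core-genome SNPs from quality-filtered
    pileups against representative genomes, and tracks strain
    transmission between hosts using rare marker alleles. Includes a
    self-contained seed-and-extend read mapper and a mock-community
    simulator that generates reference databases, strain genomes and
    error-model reads with complete ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
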