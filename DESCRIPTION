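Package: phageTermini
Title: Determination of Bacteriophage Genome Termini and Genome
    Characterization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for determining the terminal architecture of linear
    bacteriophage genomes (blunt ends, 3'- or 5'-protruding cohesive ends,
    terminal redundancy) from a circular assembly together with terminal
    run-off sequencing reads. Includes restriction-site scanning and digest
    simulation for selecting single-cutter enzymes that release terminal
    fragments, an in silico S1 nuclease check, exact direct/inverted/mirror
    repeat scanning, GC-skew profiling with replication-origin prediction,
    codon usage (RSCU) and phage-versus-host tRNA advantage analysis, genome
    dotplots, core-genome homolog counting across phage proteomes, and a
    deterministic synthetic genome generator with planted ground truth for
    validating the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: Sequencing, Genetics, Alignment, ComparativeGenomics
RoxygenNote: 7.3.3
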