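Package: circkit
Title: Classification, Junction Reconstruction and Alignment-Free
    Quantification of Circular RNA Back-Splice Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with circular RNA (circRNA) back-splice (BS)
    events in bulk and single-cell transcriptomics. Classifies BS coordinates
    against a reference transcriptome into five categories (multiexonic,
    monoexonic, putative exonic, intronic, intergenic) with univocal
    main-isoform resolution and rank-based nomenclature; reconstructs BS
    junction sequences from a genome as fixed-width windows around the
    back-splice point; quantifies junction-spanning reads in FASTQ data with a
    two-stage procedure (k-mer hash pre-selection followed by Smith-Waterman
    confirmation and best-hit counting); builds permutation and shuffle null
    sequence sets, intron-length-matched control gene pairings, divergent
    repeat-pair calls and exon-level signal-ratio scores; and simulates toy
    genomes, annotations, planted circRNAs and reads with known ground truth
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
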