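Package: condiga
Title: Contigs-Directed Gene Annotation for Metaproteomic Database Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds taxonomically annotated protein sequence databases from
    metagenomic intermediates. Implements the contigs-directed gene annotation
    strategy (MD3): contigs are taxonomically classified, the most confident
    species are selected by relative sequence abundance and genome coverage
    thresholds, and predicted genes are assigned to those species by their best
    alignment. Two baseline strategies are included for comparison (direct gene
    annotation, MD1, and contig-label propagation, MD2), together with naive
    six-frame translation databases, metagenome versus metaproteome taxon
    abundance comparison across ranks, readers for the common classifier and
    alignment formats (Kaiju, Kraken2, tabular BLAST, PAF, GFF, NCBI taxdump and
    assembly summaries), and a seeded synthetic-community generator so every
    stage runs without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
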