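Package: rnmpmapr
Title: Technique-Agnostic Mapping of Ribonucleotides Embedded in Genomic DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Locates single-nucleotide sites of ribonucleoside monophosphates
    (rNMPs) embedded in genomic DNA from reads produced by any of four rNMP
    sequencing techniques (ribose-seq, HydEn-seq, Pu-seq, emRiboSeq), then
    characterizes the sequence context and genome-wide distribution of those
    sites. Includes barcode demultiplexing, UMI extraction and position+UMI
    de-duplication, strand-aware BED coordinate arithmetic with a biological
    relevance screen, background-normalized nucleotide frequency profiles
    split by organelle, reads-per-hundred coverage tracks with BedGraph
    export, and a simulator that inverts each technique's tagging geometry so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
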