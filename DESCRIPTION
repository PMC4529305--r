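Package: potoroo
Title: Transcriptome Assembly QC, Abundance and siRNA Design for the Rat
    Kangaroo (PtK2) Transcriptome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable re-implementation of the computational pipeline behind
    a de novo transcriptome resource for rat kangaroo (Potorous tridactylus)
    PtK2 cells: read trimming and quality statistics, in-silico k-mer coverage
    normalization, assembly statistics (N50, Unigene grouping,
    cluster/singleton classification), ORF detection, read-to-transcript
    mapping with TPM/FPKM abundance estimation (simplified EM for
    multi-mappers), library complexity, alignment-based ortholog completeness
    calls, annotation-report summarization, exon-structure inference from
    mRNA-to-genome alignment, and a consensus siRNA design procedure with
    k-mer off-target screening. A seeded synthetic transcriptome and
    paired-end read generator exercises every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
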