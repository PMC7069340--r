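Package: rnaeditr
Title: Detection and Quantification of A-to-I RNA Editing in RNA-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for profiling adenosine-to-inosine (A-to-I) RNA editing
    in aligned RNA-seq data. Implements strand-aware pileup with per-base
    quality and read-end filters, a five-stage candidate filter cascade
    (quality, genomic evidence, coverage/homopolymer, frequency, mapping
    confidence/splice proximity), mismatch-spectrum summaries with a
    spectrum-based false discovery estimate, known-site interrogation, the
    overall editing index, the Alu editing index (AEI), the recoding editing
    index (REI), subsampling robustness analysis, rescue of hyper-edited
    reads by alignment to a base-transformed genome, and differential editing
    between sample groups via the Mann-Whitney U test with
    Benjamini-Hochberg correction. A seeded synthetic-data generator with a
    complete truth set makes every step testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
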