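Package: ripenrich
Title: RIP-Seq Target Identification by FPKM Enrichment with qPCR Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies protein-associated transcripts from RNA
    immunoprecipitation sequencing (RIP-Seq) experiments. Extracts read
    pairs per annotated gene region from coordinate-sorted BAM files,
    assigns fragments to transcript exon models, computes FPKM (fragments
    per kilobase of exon model per million mapped fragments), ranks
    transcripts by log2 IP-versus-input enrichment with a null-mutant
    specificity filter, and renders per-gene coverage tracks as SVG.
    Includes the qPCR arithmetic used to validate RIP targets (2^-ddCt
    relative quantification and percent-input recovery) and a seeded
    synthetic-data generator that emits annotation, spliced paired-end
    alignments and a ground-truth table so the whole pipeline can be
    exercised and benchmarked offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite
Config/testthat/edition: 3
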