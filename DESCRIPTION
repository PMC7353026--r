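Package: retroscape
Title: Structural Detection, Insertion Dating and Small RNA Attribution of
    LTR Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the transposable-element landscape of large
    plant genomes at desk scale. Provides a seeded synthetic-genome
    generator that plants full-length LTR retrotransposons of known age
    (TG...CA termini, target-site duplications, Jukes-Cantor divergence
    between the two LTR copies), a transparent structural detector for
    full-length elements with TSD validation and signature-based lineage
    labelling, Wicker-code bookkeeping with the 80 bp / 80 percent identity
    filter and genome summaries, molecular-clock insertion dating calibrated
    from cross-species synonymous divergence, best-hit attribution of small
    RNA reads to TE loci with size-class and per-superfamily profiles, and
    genomic-context utilities (gene-TE proximity, promoter extraction,
    IUPAC cis-element scanning, word dot-plots).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
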