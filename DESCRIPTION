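Package: lrgkit
Title: Locus Reference Genomic Records: Data Model, Coordinate Algebra
    and Variant Nomenclature
Version: 0.1.0
Authors@R:
    person("lrgkit", "developers", email = "lrgkit@example.org",
           role = c("aut", "cre"))
Description: Tools for building, validating and exchanging Locus Reference
    Genomic (LRG) style gene records: a two-layer record model with an
    immutable fixed-annotation layer (genomic sequence, transcripts, exon
    markup, coding regions, proteins) and a date-stamped updatable layer
    (assembly mappings, cross-references, legacy numbering, overlap
    reports).  Includes the full coordinate algebra between genomic (g.),
    coding-DNA (c., with intron offsets and UTR numbering) and protein
    (p.) positions, strand-aware mapping between an LRG and assembly or
    contig frames, parsing and formatting of HGVS-style substitution
    descriptions, conversion of deprecated IVS intron notation, XML
    serialization with a shipped schema dialect, FASTA/BED12/GFF3 export,
    synthetic record generators with exhaustive per-base truth tables,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
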