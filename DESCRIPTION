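Package: hoxminer
Title: Mining and Classifying Hox/ParaHox Genes from De Novo Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An offline, testable re-implementation of a homology-based
    protocol for recovering homeobox (Hox and ParaHox) genes from de novo
    assembled transcriptomes: six-frame ORF enumeration with a strict
    >50-amino-acid filter, evidence-vote selection of one coding sequence
    per transcript, exact-identity protein deduplication, position-specific
    scoring-matrix localization of the 60-residue homeodomain, diagnostic
    residue/motif classification into the 11 Hox and 3 ParaHox paralog
    groups of the ancestral lophotrochozoan toolkit, signature-residue
    discovery from labeled alignments, and a simplified single-copy
    marker-recovery completeness metric. A seeded synthetic-transcriptome
    generator with a machine-readable truth table makes every stage
    testable without external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    yaml,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
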