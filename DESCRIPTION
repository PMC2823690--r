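Package: regenEST
Title: EST Pipeline for Regeneration Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable re-implementation of a classical EST
    (expressed sequence tag) analysis pipeline for non-model regeneration
    transcriptomics: read cleanup (quality filtering, cloning-vector
    clipping, polyA trimming) with full flowchart accounting, greedy
    overlap-layout-consensus contig assembly with redundancy statistics,
    homology classification from BLAST-style hit tables, full-length cDNA
    and six-frame ORF calling, Gene Ontology annotation with true-path
    ancestor propagation, fold-accumulation GO enrichment with chi-square
    significance, cross-species homolog mapping through direct hits and
    shared protein identifiers, and RT-PCR densitometry analysis with
    paired t-tests. A synthetic-data module generates clone libraries,
    hit tables, toy ontologies, planted enrichment scenarios and
    densitometry tables with complete ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, SequenceAssembly, GO, Annotation
RoxygenNote: 7.3.3
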