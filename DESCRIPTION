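Package: isotigr
Title: Homology-Based Annotation, Variant Discovery and Expression Analysis
    for Assembled Transcriptome Isotigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for annotating assembled transcript consensus sequences
    (isotigs) against reference gene models of related species. Chains
    local-alignment segment pairs into syntenic hits, screens unique
    gene-level mappings with a conjunctive 2x coverage/bit-score rule,
    clusters isotigs by gene and assigns cross-species orthology-consistency
    categories. Projects reference coding regions onto isotigs to predict
    proteins and locate premature termination codons, calls biallelic
    polymorphic sites from assembly read stacks with depth, allele-fraction
    and flanking-ambiguity filters, detects non-conserved transcribed
    regions flanked by conserved alignments with an intron-realignment
    rejection filter, and tests per-gene read counts for differential
    expression between libraries with an exact conditional binomial test,
    a chi-squared test and Benjamini-Hochberg or Storey adjustment. A
    synthetic-data generator plants every feature the pipeline must
    recover, so the full analysis is testable end to end without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    fgsea,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
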