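Package: ZFNtools
Title: Design, Off-Target Scanning and Genotyping for Zinc-Finger Nucleases
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for modular zinc-finger nuclease (ZFN) experiments in
    plant genomes. Covers paired 9-bp half-site selection on a coding
    sequence, assembly of three-finger zinc-finger protein sequences from
    recognition-helix tables, reverse translation optimised under the Codon
    Adaptation Index with restriction-site avoidance, genome-wide off-target
    scanning with degenerate spacer patterns on both strands, genotyping of
    induced edits from amplicon clone sequences (variant calling, coding
    consequence, mutation-spectrum summaries), and small relative-expression
    utilities. Includes deterministic synthetic-fixture generators with
    machine-readable truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    seqinr
biocViews: SequenceMatching, Genetics, Alignment, GenomeEditing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
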