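Package: pegmave
Title: Design and Analysis of Prime-Editing Variant Effect Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for curated-locus prime-editing multiplexed
    assays of variant effect (MAVEs). Imports ClinVar and gnomAD variant
    exports, classifies variants into assay truth-set classes, designs
    engineered pegRNAs (epegRNAs) and PE3 nicking guides for curated editing
    windows, emits Golden-Gate cloning oligos and amplicon-sequencing
    primers, builds variant-identifying k-mer dictionaries, quantifies
    variants in amplicon FASTQ files by dictionary-restricted canonical
    k-mer counting, and combines per-replicate enrichment scores into a
    functional score (beta) with standard error via a DerSimonian-Laird
    random-effects model. A seeded simulator generates synthetic loci,
    variant catalogs and paired-end reads with realistic editing efficiency,
    variant dropout and selection effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
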