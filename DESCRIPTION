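Package: mutbleed
Title: Detection of Homopolymer Bleed and Mapping Artifacts in De Novo
    Mutation Call Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forensic analysis of putative de novo mutation call sets for
    sequencing and mapping artifacts. Detects homopolymer "bleed" errors
    (bases mis-read as the base of a nearby A/T homopolymeric run),
    clustered and multi-sample recurrent calls indicative of mis-mapping,
    and their downstream consequences: distorted 96-class dinucleotide
    mutation spectra, spurious equilibrium dinucleotide content, inflated
    intron-to-CDS mutation rate ratios, and artifactual mutation-rate dips
    around transcription start and termination sites. Includes a synthetic
    genome and call-set generator with a ground-truth ledger so every
    detector can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
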