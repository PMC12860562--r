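Package: seasomics
Title: Seasonal Multi-Omics Integration for Anthocyanin Regulator Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for prioritizing candidate transcription-factor
    regulators of seasonal anthocyanin accumulation from multi-omics data.
    Covers calibration-based targeted metabolite quantification and
    differential-accumulation screens; seasonal differential expression,
    pattern labelling and profile clustering; ATAC-seq peak annotation,
    differential accessibility and replicate overlap; whole-genome
    bisulfite methylation levels, differential methylation region calling
    and summit-centred methylation profiles; Hi-C matrix balancing,
    observed-over-expected transformation and A/B compartment eigenvector
    calling with three-season switch classification; and the integrative
    TF-target correlation network with four contrasting-pattern evidence
    filters and intersection ranking. Includes a deterministic synthetic
    multi-omics generator with a planted ground-truth manifest emulating a
    three-season, three-replicate study design.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
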