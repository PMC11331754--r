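Package: AntigenScape
Title: Tumor Antigen Discovery and Cohort Antigen-Landscape Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate tumor antigens from patient genomics and
    transcriptomics: neoantigens arising from somatic SNVs and indels,
    junction antigens from gene fusions, and tumor-associated antigens
    (TAAs) identified as expression outliers against a multi-organ normal
    tissue panel. Candidate peptides are enumerated per MHC class, scored
    against patient HLA alleles through a pluggable affinity backend
    (a deterministic hash-based surrogate or precomputed affinity tables),
    filtered by binding affinity, RNA variant allele fraction, expression
    and proteome novelty, and aggregated into per-patient antigen calls.
    Cohort-level analytics cover antigen burden, targetable fractions,
    recurring and shared antigens, subgroup statistics, survival
    correlation and mass-spectrometry concordance. A seeded synthetic
    cohort generator with a planted truth manifest makes every stage
    testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    openssl,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse,
    digest,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
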