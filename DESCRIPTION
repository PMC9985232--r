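Package: twinEWAS
Title: Blood-Pressure EWAS and Causal Inference in Discordant Monozygotic Twins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end epigenome-wide association pipeline for blood-pressure
    discordant monozygotic twin cohorts profiled by bisulfite sequencing. Covers
    phenotype derivation and discordant-pair selection, CpG matrix quality control
    and beta-to-M transformation, reference-free cell-type components (ReFACTor
    style), per-CpG association by pair-clustered generalized estimating equations
    with cluster-robust inference and tiered significance, autocorrelation-aware
    differentially methylated region calling in the comb-p style with
    Stouffer-Liptak-Kechris regional p-values, bidirectional ICE FALCON causal
    inference with pair-level bootstrap, nearest-gene annotation, candidate-CpG
    case-control validation, and a seeded synthetic twin-cohort generator so the
    whole pipeline is testable without access to restricted cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: DNAMethylation, Epigenetics, DifferentialMethylation, Regression
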