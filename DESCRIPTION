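Package: txcoupler
Title: Quantitative Analysis of Coupled Transcription and Translation
    During Glucose Starvation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative dissection of promoter-directed
    coupling between mRNA synthesis and cytoplasmic mRNA fate in yeast
    glucose starvation. Implements a first-order kinetic model of induced
    mRNA accumulation and decay (dX/dt = beta - alpha*X) with parameter
    inference and a classifier that discriminates transcription-rate from
    decay-rate changes; qPCR delta-delta-Ct fold changes and the
    three-stage RNA-immunoprecipitation enrichment normalization; ChIP
    coverage enrichment with strand-aware scaled metagene profiles,
    promoter-window enrichment and gene-class comparisons; reporter
    protein-synthesis rates, translatability and ribosome occupancy; and a
    co-transcriptional immunoprecipitation (CoTrIP) proteomics enrichment
    screen. Seeded generators reproduce the statistical structure of every
    input so the whole pipeline is testable on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    minpack.lm,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
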