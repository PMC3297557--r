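Package: mitonoise
Title: Mitochondrial Variability as a Source of Extrinsic Cellular Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A stochastic cell-growth and division simulator in which uneven
    inheritance of mitochondrial mass and functionality at mitosis drives
    cell-to-cell variability in ATP concentration, transcription rate, mRNA
    and protein expression, and the stability of stem-cell fate decisions.
    Provides the single-cell growth model with closed-form dynamics and
    binomial organelle partitioning, population simulators under fixed-size
    and exponential-growth protocols, analytic and exact-stochastic
    (time-inhomogeneous Gillespie) solutions for downstream gene expression
    with dual-reporter noise decomposition, and attractor-basin analysis of
    GATA1/PU.1 lineage-decision ODE models under transcription-rate
    modulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    deSolve,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
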