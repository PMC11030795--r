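Package: tmesim
Title: Agent-Based Simulation of Adoptive T Cell Therapy in the Tumor
    Microenvironment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multiscale agent-based model of adoptive CD8+ T cell therapy
    in a two-dimensional solid-tumor microenvironment. Phenotype-switching
    T cell agents (PD-1- effector-like and PD-1+ exhausted-like) and tumor
    cell agents (PD-L1-/MHC-I-low proliferative and PD-L1+/MHC-I+ quiescent)
    interact through contact-mediated engagement, delivery of cytotoxic
    packets, and a diffusing interferon-gamma field that drives tumor
    phenotype conversion. Includes a minimal compositional process/store
    simulation engine, rigid-body cell mechanics with collision resolution,
    an optional dendritic-cell/lymph-node supply compartment, initializers
    for in vitro, tumor-bed and imaging-derived experiments, a synthetic
    multiplexed-imaging table generator, and post-run statistics
    (cytotoxicity, phenotype time courses, growth-rate fits, and k-nearest
    neighbor multicellular neighborhood analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
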