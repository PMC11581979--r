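Package: condense
Title: Stability-Filtered Directed Evolution: Library Design, Screening and
    Landscape Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational machinery for stability-filtered directed-evolution
    campaigns on enzyme scaffolds. Condenses the single-substitution design
    space by filtering predicted folding free-energy changes (ddG, in Rosetta
    Energy Units), selects saturation targets from ligand-proximal shells and
    consensus variants from filtered multiple sequence alignments, plans
    oligo-pool gene fragment libraries with degenerate-codon combination
    primers and in-silico overlap-extension assembly, converts plate-reader
    traces into fold-improvement-over-parent activities and simulates the
    iterative screening campaign, fits mechanistic progress-curve models with
    conformational selection to extract kcat and Km, models DNase-I gene
    shuffling and chimera genotyping, and reconstructs two-dimensional fitness
    landscapes by principal-component embedding and radial-basis
    interpolation. A seeded synthetic-data generator emulates the statistical
    structure of a real campaign so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Biostrings,
    deSolve,
    minpack.lm,
    bio3d,
    mgcv,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Software, Proteomics, StructuralPrediction, Regression
RoxygenNote: 7.3.3
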