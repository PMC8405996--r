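Package: alloDyn
Title: Allosteric Pathway Analysis for Trimeric Proteins from Simulations,
    NMR Relaxation and Crystal Structures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative detection of allosteric communication in homotrimeric
    tautomerases of the macrophage migration inhibitory factor (MIF) family.
    Implements mutual-information-based generalized correlation of per-residue
    displacement vectors from molecular dynamics trajectories, solvent-channel
    water counting and occupancy-density mapping between gating residues,
    geometric hydrogen-bond statistics, NMR spin relaxation fitting (R1, R2,
    heteronuclear NOE, the R1R2 product) with replicate-based uncertainties,
    combined 1H-15N chemical shift perturbations with trimmed-mean outlier
    calling, and Kabsch superposition metrics for crystal structure
    comparison. A synthetic-data module generates every input class with
    known ground truth so all stages are testable without simulations or
    spectrometers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite,
    yaml,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
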