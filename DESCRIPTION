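Package: confland
Title: Conformational Landscape Inference from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds cross-validated Markov state models (MSMs) of protein
    conformational dynamics from molecular-dynamics feature trajectories:
    time-lagged independent component analysis (tICA) with kinetic and
    commute mappings, k-means microstate discretization, reversible
    maximum-likelihood transition-matrix estimation, rank-capped VAMP-2
    scoring under group shuffle-split cross-validation, implied-timescale and
    Chapman-Kolmogorov validation, and coarse-graining into kinetically
    metastable macrostates with a discrete-emission hidden Markov model.
    Downstream landscape analyses include log-inverse-flux multidimensional
    scaling embeddings, free energies, flux networks, microstate coverage
    across seed structures and simulation budgets, differential residue
    contact maps for mutant ensembles, and a two-step (induced-fit)
    ligand-binding kinetic model fitted globally to stopped-flow fluorescence
    traces. A synthetic-data generator with known hidden-Markov ground truth
    makes every stage testable without trajectory downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
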