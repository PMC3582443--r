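Package: spintraj
Title: Trajectory-Based EPR Analysis for Spin-Labeled Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of nitroxide spin-label dynamics from molecular
    trajectories: nitroxide molecular-frame construction, beta-angle
    orientational statistics with Gaussian fits and mobility parameters,
    first-derivative continuous-wave EPR spectrum simulation from
    orientation trajectories via the time-dependent spin Hamiltonian,
    inter-label distance distributions with Gaussian-mixture
    decomposition, per-residue root-mean-square fluctuations after
    rigid-body superposition, and mobility mapping into the B-factor
    column of PDB files. Includes a rotational Brownian dynamics
    generator with a uniaxial orienting potential, two-state
    mobile/immobile exchange, and helix/loop-patterned coordinate
    ensembles for end-to-end validation of the analysis chain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
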