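Package: eadclump
Title: Premature Ventricular Complexes Triggered by Clumps of EAD-Capable
    Myocytes in Monodomain Ventricular Tissue
Version: 0.1.0
Authors@R:
    person("eadclump", "developers", email = "eadclump@example.org",
           role = c("aut", "cre"))
Description: Simulates human ventricular tissue in which a spatially
    contiguous region ("clump") of early-afterdepolarization (EAD) capable
    myocytes is embedded in otherwise normal tissue, and analyses when such
    a clump triggers premature ventricular complexes (PVCs).  The myocyte is
    the O'Hara-Rudy (2011) endocardial human ventricular cell with the fast
    sodium current replaced by the Ten Tusscher-Panfilov (2006) formulation;
    EAD-capable cells are obtained by scaling the L-type calcium and rapid
    delayed-rectifier potassium conductances.  Passive (MacCannell-type)
    fibroblasts can be attached to myocytes through a linear gap-junctional
    conductance.  Tissue is an isotropic monodomain on 1D cables and 2D
    grids, integrated by forward Euler with a conservative five-point
    Laplacian, supporting heterogeneous diffusion, inexcitable point
    obstacles (diffuse fibrosis) and per-site fibroblast attachment.
    Includes seeded scenario generators, pacing and S1-S2 cross-field
    stimulation protocols, and analysis tools: AP/EAD detection and
    classification, conduction velocity, PVC counting, and averaged power
    spectra with periodic/quasiperiodic peak indexing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
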