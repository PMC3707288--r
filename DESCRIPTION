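Package: admdr
Title: Action-Derived Molecular Dynamics Pathways and Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Double-ended, least-action trajectory optimization for molecular
    systems: finds energy-conserving, near-Newtonian pathways between two
    fixed conformations by minimizing the Passerone-Parrinello action with a
    kinetic-energy restraint, using a sine-basis path parameterization with
    multigrid refinement and quasi-Newton (L-BFGS) relaxation.  Ships
    pluggable analytic and coarse-grained (Go-type) potential-energy
    surfaces, a target-energy annealing protocol, and a trajectory-analysis
    suite (radius of gyration, best-fit RMSD, native contacts, backbone
    hydrogen bonds, side-chain distances, correlations, and principal
    component analysis of C-alpha fluctuations), plus PDB/XYZ trajectory
    input and output and seeded toy-protein fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'units.R'
    'potentials.R'
    'go-chain.R'
    'trajectory.R'
    'action.R'
    'optimizer.R'
    'anneal.R'
    'campaign.R'
    'analysis.R'
    'pca.R'
    'io.R'
    'fixtures.R'
    'config.R'
    'show-methods.R'
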