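Package: lipsite
Title: Lipid Binding-Site Analysis for Pentameric Ligand-Gated Ion Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies fatty-acid interactions with pentameric ligand-gated
    ion channels from coarse-grained membrane simulations and functional
    assays. Provides leaflet-resolved polar density and enhancement maps,
    the boundary lipid metric, per-residue lipid contact probabilities,
    annular-sector binding-site occupancy histograms and density threshold
    affinities, continuous-time Markov gating-scheme current simulations for
    inhibitor pre-application protocols, biexponential current-decay and
    Hill dose-response fitting, and photoaffinity-label quantification from
    extracted-ion-chromatogram areas. A seeded synthetic-data module
    generates membrane trajectories with planted site enrichment, current
    traces, and labeling tables with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    arrow
Config/testthat/edition: 3
RoxygenNote: 7.3.3
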