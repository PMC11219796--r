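Package: voxflex
Title: Voxel-Level Protein Flexibility Prediction from Cryo-EM Maps and
    Atomic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-voxel and per-residue root-mean-square fluctuation
    (RMSF) of proteins from a cryo-EM density map and its fitted atomic model,
    using a 3D nested-Unet (Unet++) regression network trained on
    ensemble-derived fluctuation labels. Provides MRC2014 map input/output and
    resampling, simulated density rendering from atomic models, box
    segmentation/screening/normalization and merging, ensemble RMSF label
    generation with Kabsch superposition, an occupancy classifier and its
    two-stage composition with the regression network, training with masked
    mean-squared-error loss and flip augmentation, cross-validation and
    correlation metrics, and a synthetic-data generator producing
    pseudo-proteins, fluctuation ensembles with known amplitudes and
    heterogeneity-blurred noisy maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
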