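Package: bmRSA
Title: Searchlight Representational Similarity Analysis of Multidimensional
    Biological Motion fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, fully synthetic implementation of a multivariate
    fMRI pipeline for studying how facing direction, gender and emotional
    state conveyed by point-light biological motion are encoded in the
    brain. Generates parametric point-light walker stimuli on a 2x2x2
    attribute crossing, approximates early visual responses with the S1/C1
    stages of the HMAX model, simulates block-design BOLD acquisitions with
    planted multivoxel attribute structure, fits run-wise general linear
    models, and runs searchlight multiple-regression representational
    similarity analysis with theoretical and V1-model predictor RDMs,
    sign-flip Monte Carlo cluster correction, scrambled-RDM hierarchy
    analysis with Dice overlap, leave-one-run-out linear SVM decoding, and
    behavioral-to-neural RDM linkage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
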