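Package: BulbFeedback
Title: Cortical GABAergic Feedback to the Olfactory Bulb: Rate Model and
    Calcium-Imaging Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying long-range inhibitory (GABAergic) cortical
    feedback to the olfactory bulb. Implements a two-population
    excitatory-inhibitory firing-rate model of the mitral/tufted-cell and
    granule-cell circuit with nullcline and fixed-point analysis and
    parameter-grid sweeps of feedback-induced rate changes; a trial-based
    two-photon calcium-imaging pipeline (out-of-plane frame detection,
    Fourier-based translational motion correction, PCA-assisted movie
    reconstruction, within-ROI PCA refinement, trace extraction, z-score
    response statistics and paired-test response classification); a fiber
    photometry pipeline (smoothing, downsampling, per-trial dF/F,
    reflected-light quality control, net light-impact quantification);
    population-vector Euclidean-distance statistics for odor-separation
    analysis; and a seeded synthetic-data generator producing
    ground-truth-labeled movies, trace sets and photometry sessions with the
    trial structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
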