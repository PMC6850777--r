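Package: yeastGLM
Title: Genome-Level Missegregation Analysis for Yeast Replicative Aging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, event calling and cohort statistics for genome-level
    missegregation (GLM) events observed in single budding-yeast mother cells
    aged in microfluidic devices. Provides a phenomenological cohort generator
    with ground-truth events and histone-fluorescence traces, a microscopy
    calibration pipeline (dark-frame bias and flat-field correction, top-2%
    asymmetry scores), an automated event caller for mother/daughter trace
    pairs, and censoring-aware aging statistics: age-aligned event-probability
    curves, Kaplan-Meier survival with log-rank tests, Cochran Q trend tests,
    calibrated percentile-bootstrap intervals, history dependence and
    counterfactual lifespan gain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    flexsurv,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: SingleCell, Survival, Software, CellBiology
RoxygenNote: 7.3.3
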