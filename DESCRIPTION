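Package: epsctools
Title: Quantification of Sustained EPSC Responses and Glutamate Receptor
    Currents in Voltage-Clamp Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for whole-cell voltage-clamp recordings from
    brainstem slice preparations: threshold-based detection of spontaneous
    excitatory postsynaptic currents (EPSCs), peristimulus frequency
    histograms and the duration of burst-evoked sustained EPSC responses,
    rectification-index classification of Ca2+-permeable AMPA receptor
    currents, NMDA/AMPA ratio and capacitance-normalized charge transfer,
    series-resistance quality control, and a normality-gated statistical
    battery (Shapiro-Wilk gating of t versus rank tests, Kolmogorov-Smirnov
    distribution comparison, post hoc power from the noncentral t
    distribution).  Includes a synthetic trace generator with inhomogeneous
    Poisson synaptic events and known ground truth for validating every
    stage of the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
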