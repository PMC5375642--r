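Package: tectomsi
Title: Multisensory Integration Analysis for the Tadpole Optic Tectum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for quantifying multisensory integration and
    inverse effectiveness in the Xenopus tadpole optic tectum across three
    levels of measurement. Implements calcium-imaging trace extraction
    (motion registration, neuropil subtraction, bleach correction, dF/F0,
    three-point peak estimation), the multisensory index (MSIn) with the
    0.1 response-inclusion rule, and exponential-decay fits of MSIn against
    unisensory response size; behavioral swim-speed and startle-rate MSIn
    with their ANOVA, Dunnett, Sidak, ANCOVA and Tukey batteries; and
    single-cell electrophysiology quantification (threshold spike detection,
    response areas, sub/suprathreshold classification, linear-sum versus
    crossmodal comparison, exact Mann-Whitney tests). A synthetic-data
    generator produces calcium movies, behavioral trial tables and synaptic
    traces with known ground truth and a tunable NMDA-like supralinear
    summation rule, so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    minpack.lm,
    multcomp,
    emmeans,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
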