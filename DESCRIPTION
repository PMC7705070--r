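Package: floravision
Title: Perceptual Modeling of Intrapopulation Floral Colour Variation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models flower reflectance spectra in pollinator visual spaces and
    quantifies how much within-population colour variation each viewer can
    perceive. Implements the honeybee colour hexagon and the receptor-noise
    limited (RNL) model for tetrachromatic birds, computes adapted quantum
    catches under a D65 illuminant with von Kries adaptation, derives pairwise
    colour distances and the fraction of flower pairs above each viewer's
    discrimination threshold, and fits linear mixed-effects models testing
    whether perceived variation depends on the visual system by pollination
    system interaction. Includes a synthetic floral-spectra generator with
    Gaussian-peak (bee-type) and long-pass sigmoid (red, UV-free bird-type)
    archetypes for end-to-end simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmerTest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
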