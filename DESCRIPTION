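Package: peritex
Title: Summary-Statistics Modeling of Peripheral Texture Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying contextual modulation of naturalistic texture
    perception in peripheral vision within the summary-statistics framework.
    Implements a complex steerable-pyramid decomposition, Portilla-Simoncelli
    summary statistics pooled over a Bouma-law window, construction of
    texture-discrimination stimuli (phase scrambling, spectrum and histogram
    matching, target/surround geometries with segmentation cues), an
    image-computable model observer for the three-alternative forced-choice
    texture discrimination task based on a cross-validated penalized
    multinomial classifier, and log-odds-ratio analysis of trial data with
    binomial mixed models. Includes procedural texture and behavioral-data
    generators so the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    lme4,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
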