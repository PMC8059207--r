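Package: dnacondense
Title: DNA Length-Dependent Condensation: Phase-Diagram Theory and
    Condensate Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how DNA length controls the formation and
    material state of DNA condensates. Implements the Post-Zimm extension
    of Flory-Huggins theory for single-chain coil-globule collapse and
    two-phase coexistence (binodal) of DNA solutions, fitting of
    fluorescence recovery after photobleaching (FRAP) curves, condensate
    segmentation and aspect-ratio morphometry with fluidity-class
    clustering, intensity-decay analysis of surface-anchored condensates
    under buffer flow with intensity-based molecule counting, and
    deterministic synthetic-data generators with known ground truth so
    that every analysis stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
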