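Package: vftrain
Title: Simulation and Evaluation of Adaptive Visual-Field Training in a VR Headset
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A headless re-implementation of the computational core of a
    virtual-reality visual-restitution training device. Provides coordinate
    conversion between a perimeter's screen plane and a head-mounted display's
    angular space, parametric visual-field maps with scotomata (including the
    physiological blind spot), a feedback-driven stimulus-relocation trainer
    that tracks the border between intact and defect visual field, a stochastic
    simulated observer, the blind-spot validation study protocol, and a full
    detection-metrics suite (sensitivity, specificity, predictive values, hit
    rate, chance-level random hit rate, RATZ index, accuracy, and split-half
    reliability with Spearman-Brown correction), plus session logging and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
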