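Package: conformsim
Title: Similarity-Conditioned Social Learning: Coevolutionary Model and
    Urn-Experiment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for studying the evolution of facultative conformist social
    learning conditioned on perceived similarity between naive learners and
    experienced demonstrators. Implements a closed-form Bayesian decision model
    in which a learner combines a noisy private signal about her own
    environmental state, the distribution of behaviors in a sample of
    demonstrators, and a noisy binary cue of similarity; a gene-culture
    coevolutionary simulator in which the heritable cognitive representations
    behind that rule evolve under Wright-Fisher selection while the behavior
    frequency evolves culturally; a synthetic generator for two-urn social
    learning experiments with demonstrator and social-learner roles; and the
    corresponding analysis pipeline (cluster-robust logistic regressions, Wald
    tests of linear combinations, per-learner strategy classification, and
    cluster-bootstrap learning curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    sandwich,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
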