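Package: capdce
Title: Discrete Choice Experiment Toolkit for Capitation Payment Preferences
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Design, simulation and estimation tools for stated-preference
    discrete choice experiments (DCEs) on health provider payment mechanisms.
    Implements attribute/level schemas with numeric utility coding,
    D-efficient unlabelled design generation by coordinate exchange under
    point priors, random-utility choice and ranking simulation, multinomial
    logit (MNL) and panel mixed logit (MMNL) maximum-likelihood estimation
    with classical and cluster-robust covariance, and post-estimation
    statistics: delta-method willingness-to-accept and attribute
    relative-importance scores.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
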