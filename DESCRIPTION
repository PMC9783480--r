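Package: sexplast
Title: Meta-Analysis of Sex Differences in Thermal Plasticity of Insect Development Time
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying sex differences in temperature-induced
    plasticity of insect development times from treatment-level literature
    data. Computes log-transformed reduced major axis (RMA) regression slopes
    of male on female development time as effect sizes, sexual development
    time dimorphism (SDTD), bootstrap sampling variances and inverse-variance
    weights, and fits phylogenetic multilevel mixed-effects meta-analytic
    models by REML with permutation-based inference, including a paired
    sign-flip comparison of temperature- versus diet-induced sex differences.
    A synthetic-data generator reproduces the statistical structure of the
    literature-derived corpus so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
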