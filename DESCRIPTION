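Package: aquatherm
Title: Quantifying Behavioral Thermoregulation in Aquatic Ectotherms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying behavioral thermoregulation in small
    aquatic ectotherms from thermal-gradient preference trials and
    depth-stratified water-column temperature records. Estimates
    preferred-temperature (Tp) ranges as percentile boundaries of gradient
    body temperatures, builds interpolatable operative-temperature (Te)
    profiles from datalogger series, computes the thermoregulatory indices
    de (thermal quality of habitat), db (accuracy of thermoregulation) and
    E (effectiveness, difference and ratio forms) at hourly resolution,
    and provides permutation pseudo-F tests, non-parametric bootstrap
    confidence intervals and variance decompositions for inference. A
    synthetic-study generator simulates stratified water columns with a
    curvilinear daytime warming trend and behavioral agents (active depth
    selection versus temperature-independent depth use) so that every
    pipeline stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
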