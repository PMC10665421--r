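Package: gapmech
Title: In Silico Fracture Trials and Fracture Gap Micromechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for virtual (in silico) clinical trials in
    surgical fracture care. Generates an anthropometric avatar population from
    age-stratified truncated normal distributions, rescales stance-phase gait
    load landmarks to each avatar's body weight, evaluates strain tensor fields
    over a tibial fracture gap and callus region with a documented
    parallel-spring surrogate of the bone-nail construct, computes the strain
    invariants relevant to mechanoregulated healing (hydrostatic strain,
    octahedral shear strain, maximum principal strain, J2), correlates
    anthropometric parameters with the gap micromechanics, and quantifies via
    cohort resampling how often randomized trial cohorts differ significantly
    and relevantly (two-sample t-test plus Cohen's d stopping rule) in their
    anthropometric makeup.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
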