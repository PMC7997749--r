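Package: admitplan
Title: Patient-Mix Admission Planning under Resource and Priority Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tactical admission planning for elective patients in capacity-
    constrained hospital departments. Builds and solves an integer program
    that chooses how many patients of each type to admit on each day of a
    planning cycle, maximizing revenue net of goal-programming deviation
    costs for bed, medical-examination and nursing capacity. Length of stay
    is stochastic and enters through survival-curve census expectations.
    Includes instance file readers and writers, a packaged case-study
    instance, scenario sweep and model-comparison engines, a synthetic
    instance generator, a brute-force enumeration oracle and a Monte-Carlo
    discharge simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
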