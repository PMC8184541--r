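Package: fracrisk
Title: Country-Specific Fracture Probability Models Under Competing
    Mortality
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for constructing country-specific osteoporotic fracture
    risk models from age- and sex-specific hip-fracture incidence and
    national mortality rates: surrogate major-osteoporotic-fracture (MOF)
    incidence via hip-to-MOF ratio schedules, 10-year first-fracture
    probabilities under the competing risk of death computed exactly on
    piecewise-constant hazards, multiplicative clinical risk-factor and
    BMD adjustment, age-standardisation to a user-supplied standard
    population, cross-population comparison statistics, and a synthetic
    Gompertz-Makeham data generator so every pipeline stage is testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
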