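Package: protindex
Title: Composite Protective Index Analysis for Defensive Symbiosis Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying symbiont-mediated protection of insect hosts
    against parasitoid attack as a composite Protective Index (PI): the ratio of
    survival x proportion fertile x mean fecundity of fertile survivors between
    wasp-exposed and unexposed symbiont-carrying hosts. Provides exact binomial
    group summaries, simulation-based 95% credible intervals for PI from beta
    and truncated-normal posteriors, posterior strain-ordering probabilities,
    factorial GLM term tests with stepwise model simplification, a
    separation-robust Cauchy-penalized logistic regression, Box-Cox transformed
    linear models, wing-landmark polygon morphometrics, and a synthetic-data
    generator emulating a full host x symbiont x parasitoid-strain x ethanol
    factorial assay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    car,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
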