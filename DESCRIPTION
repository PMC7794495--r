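Package: owlfam
Title: Delayed Dispersal and Family Living in Urban and Rural Bird Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying delayed natal
    dispersal and family-unit formation in a territorial bird occupying
    urban and rural habitats. Provides a seeded individual-based population
    simulator; spatial conspecific aggregation and neighbourhood-productivity
    indices; GLM/GLMM fitting with AICc model selection and full-model
    averaging; a Cormack-Jolly-Seber capture-mark-recapture likelihood engine
    with age classes, groups, time and effort effects and individual
    covariates; permutation and encounter-history resampling procedures; and
    likelihood-based microsatellite relatedness classification and parentage
    assignment. Readers and writers for MARK encounter-history (.inp) and
    GenePop genotype files are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmmTMB
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
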