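Package: dimix
Title: Multi-Year Diversity-Interactions Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits Diversity-Interactions (DI) models to multi-year
    biodiversity-ecosystem-function data. Species proportions enter as
    identity effects and products of proportions as interaction effects
    (average pairwise, functional group, additive species, or full
    pairwise parameterizations), optionally crossed with a spatial
    planting-pattern treatment or scaled by a covariate such as legume
    percentage. Pairwise interaction lack-of-fit is modelled through
    random effects indexed by species pair and year, with heterogeneous
    repeated-measures residual covariance (compound symmetry, AR(1) or
    unstructured blocks, optionally differing across plot groups).
    Includes boundary-corrected likelihood-ratio tests for variance
    components, a stepwise model-selection workflow, experimental-design
    generators, and a power / type-I-error simulation study engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), nlme, lme4, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
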