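Package: ambientgxe
Title: Ambient Pesticide Exposure Assessment and Gene-Environment
    Interaction Analysis for Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for gene-environment interaction
    analysis in case-control studies of ambient pesticide exposure.
    Implements a GIS-style exposure-assessment procedure (annual
    pounds-per-acre sums within a buffer radius of residential and
    occupational addresses, study-window averaging with imputation of
    un-geocoded years, and median-based dichotomization in exposed
    controls), Hardy-Weinberg equilibrium tests (chi-square and exact),
    additive/recessive/homozygote genotype coding, multiplicative
    interaction logistic models fitted by iteratively reweighted least
    squares with Wald and likelihood-ratio inference, and
    simulation-based power estimation. A synthetic cohort generator
    emulating pesticide-use-report records, address histories, and
    genotypes in Hardy-Weinberg equilibrium makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
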