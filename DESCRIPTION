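Package: matingkit
Title: Mating System Estimation from Progeny Arrays in Mixed-Mating Plant
    Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates multilocus outcrossing (tm) and selfing (s = 1 - tm)
    rates per maternal family from codominant progeny-array genotypes by
    Expectation-Maximization under the mixed-mating model, with
    maternal-genotype inference, family-level bootstrap standard errors,
    inbreeding coefficients across generations (adult F, equilibrium Fe,
    and the purging statistic Fe - F), inbreeding depression from paired
    self/outcross pollination experiments, the primary selfing rate
    correction r = s/(1 - delta + s*delta), and association analyses of
    mating-system parameters with herkogamy (variance components, beta
    regression with link selection, Gaussian models, ANCOVA,
    correlations). Includes a forward simulator of progeny arrays,
    herkogamy measurements and crossing-experiment fitness records for
    parameter-recovery validation, and GenePop/TSV input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    nlme,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
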