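Package: beesim
Title: Stochastic Long-Term Simulation of Honeybee Breeding Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulator of closed honeybee breeding programs for a
    single trait with negatively correlated direct (worker) and maternal
    (queen) genetic effects. Provides interchangeable finite-locus and
    infinitesimal genetic engines, exact haplodiploid pedigree bookkeeping
    with individually tracked drones, yearly bivariate pedigree BLUP via
    sparse mixed-model equations, truncation selection on colony estimated
    breeding values, and reporting of genetic gain, variance erosion,
    inbreeding, estimation bias and the number of Monte Carlo repetitions
    required for a given precision.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
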