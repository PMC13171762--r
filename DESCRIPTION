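Package: femcost
Title: Fitness Costs of Symbiont-Mediated Feminization in XX/X0 Hosts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the reproductive fitness cost that a feminizing,
    maternally transmitted endosymbiont imposes on a host with XX-female /
    X0-male sex determination. Implements the karyotype-transmission
    recursion and its equilibrium, expected undeveloped-egg proportions
    with multiplicative background mortality, seeded Monte Carlo
    confidence intervals for brood-level mortality statistics, grouped
    binomial logistic regression with Williams' overdispersion correction
    and deviance-difference tests, one-way linear models with planned
    contrasts and Tukey-Kramer compact letter displays, and a synthetic
    brood-data generator emulating a six-symbiotype spider experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
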