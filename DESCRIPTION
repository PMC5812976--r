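Package: cultherit
Title: Gene-Culture Transmission Dynamics and Twin-Based Heritability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic recursion of six phenogenotype frequencies for a
    diallelic locus with a dichotomous phenotype under vertical cultural
    transmission and partial phenotypic assortative mating.  Solves for the
    equilibrium phenogenotype distribution, enumerates exact joint phenotype
    distributions for spouse, parent-offspring and twin pairs, decomposes the
    equilibrium phenotypic variance into its additive genetic component, and
    contrasts the actual narrow-sense heritability with the classical
    twin-correlation (Falconer) estimators, which cultural transmission can
    inflate.  Includes a seeded finite-population forward simulator as an
    independent stochastic oracle and a synthetic twin-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
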