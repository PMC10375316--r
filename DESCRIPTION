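Package: h295calux
Title: Analysis of Coupled H295R-CALUX Endocrine Activity Screens
Version: 0.1.0
Authors@R:
    person("Plate", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for the coupled H295R steroidogenesis /
    ERalpha and AR U2OS CALUX reporter-gene screen: reads long-format
    96-well luminescence tables, normalizes raw relative light units to
    percent viability, percent relative induction and percent of basal
    hormone production, applies plate quality-control criteria (limit of
    quantification, induction factor, Z-factor, four-parameter logistic
    standard-curve fits, coefficient-of-variation checks), determines
    lowest observed effect concentrations by pooled Kruskal-Wallis and
    Mann-Whitney testing, classifies chemicals as steroidogenesis
    modulators, direct receptor (ant)agonists or cytotoxicity-confounded,
    and evaluates concordance against reference classifications with
    direction-aware confusion matrices. Includes a five-plate synthetic
    data simulator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
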