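Package: wfmr
Title: Within-Family Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Within-family Mendelian randomization estimators and a
    forward-in-time family simulator. Simulates mother-father-offspring
    families under dynastic effects, assortative mating and population
    stratification; estimates per-SNP associations by unrelated-sample
    ordinary least squares, sibling differences, family fixed effects and
    parental-genotype adjustment in trios, all with family-clustered
    sandwich standard errors; fits polygenic-score two-stage least squares
    with optional family fixed effects; and pools summary statistics with
    inverse-variance weighting, MR-Egger, weighted median and weighted
    mode estimators, including seemingly-unrelated-regression shrinkage of
    total to within-family associations. A study driver reproduces false
    discovery rate, power and bias simulation grids comparing unrelated,
    sibling and trio designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
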