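Package: metstab
Title: Multi-Environment Trial Analysis of Photoperiod-Driven Phenology and
    Yield Stability in Durum Wheat
Version: 0.1.0
Authors@R: person("MET", "Tools", email = "met@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for quantitative analysis of durum wheat
    multi-environment trials: phenology-windowed environmental covariates
    (day length with twilight, photo-thermal units, temperature and radiation
    aggregates), combined ANOVA with a nested split of the genotype sum of
    squares into photoperiod allele-combination and within-combination
    (earliness per se) components, per-experiment REML/BLUP isolation of
    earliness-per-se effects and their correlations with yield formation,
    five genotype-by-environment yield-stability indices (Finlay-Wilkinson,
    Lin-Binns, Shukla, Wricke, Kang rank-sum), and a correlation-matrix PCA
    of environment characterisations.  Includes a synthetic trial generator
    with known ground truth emulating a 3-site x 5-year x 23-genotype
    randomised complete block design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lme4,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
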