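Package: robustqtl
Title: Genetic Mapping of Phenotypic Robustness QTL in Inbred Strain Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci that affect the
    robustness (dispersion) of a phenotype rather than its mean, in panels of
    replicated inbred strains.  Genetic-robustness (GR) QTL are detected with
    the median variant of the Fligner-Killeen rank dispersion test applied to
    strain medians; environmental-robustness (ER) QTL are detected by
    correlating within-strain variability with marker genotype.  Includes
    median-QTL exclusion filters, strain-label permutation significance and
    false-discovery rates, cis/trans classification of expression-trait hits,
    power and expected-overlap estimation, variance-ratio replication tests,
    confounding diagnostics, and a synthetic strain-panel simulator with
    planted ER/GR effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
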