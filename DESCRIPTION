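Package: trophicstrat
Title: Trophic Stratification of Species Richness with Uncertainty Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how species richness is distributed across
    trophic levels. Classifies species into primary, mixed and higher-level
    consumers from taxon-level diet records using a rule set that propagates
    verbal-descriptor and diet-interval uncertainty through Monte Carlo
    replication, builds trophic pyramids of species richness with confidence
    intervals, assembles per-pixel communities on a one-degree grid, and tests
    whether trophic-level ratios are uniform across community trophic
    structures via linear discriminant analysis of arcsine-square-root
    transformed proportions and one-way ANOVA variance decomposition. Includes
    a synthetic-data generator with controllable ground truth for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
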