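Package: smlmpp
Title: Point-Pattern Analysis of Two-Color Single-Molecule Localization Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying receptor nanoclustering and two-channel
    segregation from single-molecule localization microscopy (SMLM) point
    patterns, as used to study chimeric-antigen-receptor (CAR) organization
    at CAR-T/target-cell interfaces. Reads ThunderSTORM-style localization
    tables, corrects blinking over-counting by spatiotemporal merging,
    estimates univariate and bivariate pair-correlation functions with
    toroidal or border edge correction, computes the extent-of-mixing (EOM)
    statistic and its segregation companion, identifies nanoclusters by
    DBSCAN and reports monomer/dimer/oligomer size distributions, tests
    axial (z) separation of the two channels, and aggregates per-cell
    statistics into per-condition summaries with normalized parameter
    correlation matrices. A seeded synthetic-data generator (CSR and Thomas
    processes with configurable co-clustering, segregation, random
    labelling, blinking and localization error) provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
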