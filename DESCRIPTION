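Package: elevshift
Title: Elevational Range-Shift Analysis for Two-Period Resurvey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating elevational range shifts of species
    between a historical survey and a modern resurvey of the same sites.
    Computes three range points per species and period (lower limit, upper
    limit and abundance-weighted range centre), standardizes unequal
    sampling effort by repeated per-site subsampling without replacement,
    tests per-species shifts with paired-replicate t tests and
    community-level trends with Wilcoxon signed-rank tests, and relates
    upslope shifts in range centres to ecological traits through
    all-subsets AICc model selection with model averaging.  A synthetic
    two-period survey generator with known true shifts supports
    parameter-recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
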