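Package: hdxdiff
Title: Differential Hydrogen-Deuterium Exchange Mass Spectrometry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for peptide-level differential hydrogen-deuterium exchange
    mass spectrometry (HDX-MS). Normalizes centroid masses to percent exchange
    against a fully-deuterated standard, pools replicate standard deviations
    into a global confidence limit for differential uptake, classifies
    peptides and sequence regions as stabilized or destabilized, and exports
    Woods-plot data. Includes an EX2 kinetic simulator with back-exchange and
    nested replicate noise for end-to-end validation, plus utilities for
    plate-reader kinetics (sigmoid time-to-half-maximum, standard-curve
    quantification of enzyme activity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    stats,
    utils,
    withr,
    yaml,
    minpack.lm,
    generics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
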