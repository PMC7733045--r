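Package: health2020
Title: Composite Health 2020 Index Construction for the WHO European Region
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds the Health 2020 composite index from long-format
    country-by-indicator-by-year panels: resolves observations onto the
    2005/2010/2015 reference years with a nearest-year substitution rule,
    applies the missing-data country filter, rescales quantitative
    indicators between pooled goalposts onto a 1-100 scale, aggregates
    them by policy target and overall with geometric means under explicit
    missing-data policies, classifies countries into index quintiles, and
    summarises per-indicator relative change by quintile. Ships an
    editable indicator/target registry and a synthetic panel generator
    with known ground truth so the whole pipeline is testable without
    access to the underlying WHO databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
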