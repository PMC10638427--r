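Package: apmshits
Title: Hit Identification for AP-MS Screens with Double Negative Controls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies specific bait-prey interactions in affinity
    purification mass spectrometry (AP-MS) screens that use a double
    negative-control design (an untagged strain capturing resin binders and
    a heterologously tagged strain capturing tag binders). Implements a
    qualitative strategy based on triplicate presence/absence set algebra
    and a quantitative strategy based on median-normalized log10
    intensities, condition-wide global standard deviation, one-sided
    z-scores and Benjamini-Hochberg correction. Ships a synthetic AP-MS
    data generator with planted ground truth, condition-resolved
    interaction-network export (SIF/GraphML/TSV), replicate- and
    condition-overlap summaries, bait-similarity matrices and volcano
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
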