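Package: smrgrowth
Title: Single-Cell Growth Analysis for Suspended Microchannel Resonator Mass Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-cell buoyant-mass time series measured
    with a suspended microchannel resonator (SMR): detection and calibration of
    resonance-frequency transit peaks, assembly of per-cell mass traces across
    generations, annotation of cell-cycle events (mitotic entry,
    metaphase-to-anaphase transition, abscission), correction of the
    cytokinetic elongation bias using a second-bending-mode cantilever model,
    sliding-window estimation of mass accumulation rate (MAR) and
    mass-normalised MAR, ensemble alignment and averaging across cells, and a
    ground-truth lineage simulator for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
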