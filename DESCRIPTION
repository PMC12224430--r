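Package: pecmap
Title: Meta-Modeling of Brain Stimulation Dose-Response via
    Performance-Electric-Field Correlation Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-modeling the relationship between transcranial
    direct current stimulation (tDCS) electric-field distributions and
    behavioral effect sizes. Computes bias-corrected standardized effect
    sizes (Hedges' g) from condition summary statistics, assembles
    node-by-outcome electric-field matrices from per-montage field maps,
    derives node-wise performance-electric-field correlation (PEC) maps
    with robust-maximum summaries, and assesses significance by
    permutation testing with atlas-parcel aggregation (75th-percentile
    rule). Includes a synthetic-data generator that emulates montage
    dependent field maps and outcome corpora with planted effects, so the
    full pipeline is testable end to end without head-model simulations.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
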