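Package: sleepscape
Title: Sleep Phenotype Landscapes and Their Temporal Dynamics from
    Wearable Hypnograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts epoch-level (30-second) sleep-stage series from
    wearable devices into long and short sleep windows and nine nightly
    sleep-architecture features, assembles non-overlapping 3-6-night sleep
    periods, embeds and clusters the 18-dimensional period features into a
    two-dimensional sleep landscape (UMAP + DBSCAN) with rule- and
    geometry-based subdivision into 13 sleep phenotypes, models
    within-individual phenotype change as a conditional-transition-
    probability graph, and quantifies how much more information those
    transition dynamics carry about chronic and acute health conditions
    than static phenotype membership (chi-square tests and information
    gain). Includes a seedable synthetic-hypnogram generator with known
    latent phenotype dynamics so that every stage of the pipeline is
    testable without access to proprietary wearable data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
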