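Package: liftkin
Title: Canopy Chlorophyll-Fluorescence Kinetics and Phenotyping Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing and modelling pipeline for light-induced
    fluorescence transient (LIFT) canopy phenotyping campaigns. Extracts
    photosystem II efficiency (Fv/Fm, Fq'/Fm') and electron-transport
    efficiency statistics (Fr1/Fv, Fr2/Fv) from fast-repetition-rate
    flashlet transients, computes canopy reflectance indices with
    PPFD-keyed grey-reference correction, applies campaign quality
    filters, links measurements to minute-resolution environmental
    records, and models genotype-by-environment responses with
    L1-penalised regression and sequential sum-of-squares variance
    partitioning. Includes a seeded synthetic-campaign generator so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    glmnet,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
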