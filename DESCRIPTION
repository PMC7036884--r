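Package: odontosurvey
Title: Oral-Health Epidemiological Survey Data: Odontograms, Caries
    Indices, Examiner Calibration and Field-Batch Synchronization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for school-based dental caries surveillance surveys:
    validation of WHO-style odontograms coded with a two-track
    crown/treatment alphabet, computation of the DMFT (CPO-D) and ceo-d
    caries indices with grouped aggregation by school, health territory,
    sex and age, inter-examiner calibration against team consensus via
    weighted Cohen's kappa with an acceptance gate, offline field-batch
    capture with idempotent merge into a central store, territory
    assignment and participation/desk reports, CSV/JSON/XML export with
    lossless round trip, and a seedable synthetic survey generator with
    known ground-truth parameters for testing the whole pipeline offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    xml2,
    mgcv,
    graphics,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
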