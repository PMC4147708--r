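Package: foodswap
Title: Traffic-Light Labelling, Nutrient-Profile Scoring and Healthier-Swap
    Recommendations for Packaged Foods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engine for interpretive front-of-pack nutrition labelling of
    packaged foods. Maintains a barcode-keyed branded food composition
    database; classifies total fat, saturated fat, sugars and salt as
    green/amber/red against UK FSA-style per-100 g/ml and per-portion
    thresholds; computes FSANZ-style nutrient-profile scores (baseline points
    for energy, saturated fat, sugars and sodium, offset by modifying points
    for fruit/vegetable/nut/legume content, protein and fibre); imputes
    missing fibre, calcium and fruit-and-vegetable values from category-level
    rules; ranks same-category products with more favourable scores as
    healthier switches (including a sodium-first mode); and queues
    crowdsourced submissions for barcodes missing from the database. A seeded
    synthetic database generator makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
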