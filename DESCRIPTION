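Package: hrvagree
Title: Agreement of Wearable Heart-Rate Sensors with Criterion ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for validating beat-to-beat heart-rate data from
    photoplethysmography (PPG) wearables against a criterion
    electrocardiogram. Ingests timestamped interbeat-interval (IBI)
    exports, synchronizes device and criterion clocks by
    cross-correlation, segments recordings into experimental conditions,
    corrects artifacts with a range filter and the Karlsson neighbor-mean
    rule with per-participant adaptive thresholds, extracts mean heart
    rate, RMSSD and high-frequency spectral power, grades signal quality,
    summarizes wrist acceleration, and quantifies device-criterion
    agreement with MAAPE, ordinary least-squares regression and
    Bland-Altman limits of agreement. A paired-stream simulator with
    known ground truth makes the full pipeline testable without any
    recorded data.
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
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
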