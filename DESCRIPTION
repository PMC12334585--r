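Package: tamotif
Title: Temporal Activity Motifs from Check-In Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines temporal activity motifs from location-based social
    network check-in data. Raw check-in events are cleaned, mapped to seven
    activity types, and segmented into daily (5 AM-anchored) run-merged
    activity-type sequences. Typed temporal patterns of one to four
    transitions -- both sequential (temporal walks) and non-sequential
    (co-occurring processes sharing a node) -- are enumerated and counted by
    the number of distinct daily sequences containing them, selected as
    motifs by dual frequency thresholds, and summarised with motif coverage
    ratio (MCR) and cumulative occurrence ratio (COR) metrics. Includes a
    Markov-chain check-in simulator with plantable patterns so the whole
    pipeline is testable without external data, and exporters for the
    transition-distribution tables used in downstream analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
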