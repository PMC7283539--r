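Package: phenofrag
Title: Impact of Data Fragmentation on EHR Computational Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how data fragmentation across healthcare
    institutions degrades EHR-based computational phenotyping. Implements a
    regression-scored rheumatoid arthritis (RA) case/control algorithm and a
    rule-based type 2 diabetes mellitus (T2DM) case/control algorithm over a
    multi-source clinical event model, evaluates each single-source view
    against the deduplicated union of sources as benchmark
    (sensitivity, specificity, PPV, false-negative rate), and attributes every
    benchmark disagreement to the clinical evidence missing from the erring
    source. Ships a configurable synthetic multi-institution EHR cohort
    generator so the full pipeline is testable without protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
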