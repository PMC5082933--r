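Package: tcgavault
Title: Versioned Acquisition, Harmonization and Provenance Management for
    TCGA-Style Genomic Archives
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained engine for mirroring multi-source genomic
    data archives into a versioned, participant- and sample-centered local
    repository.  Detects added, modified and deleted files per source
    strategy (serial-numbered archives with change lists, or date-keyed
    stores), fetches with MD5 verification and retry, validates and
    harmonizes VCF payloads against a fixed header standard, names files
    with an informative thirteen-component grammar built on the TCGA
    barcode, and maintains a provenance metadata store supporting
    manifests, date snapshots, subscriptions, notification events and JSON
    change messages.  A deterministic fixture generator emulates the four
    upstream source dialects so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    jsonlite,
    yaml,
    generics,
    ggplot2,
    tools,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
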