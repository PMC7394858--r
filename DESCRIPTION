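Package: lizmet
Title: Heavy-Metal Biomonitoring Indices from Lizard Tail Tissue
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ecotoxicological biomonitoring pipeline for heavy-metal
    (Pb, Cu, Ni, Zn, Cd) concentration surveys that use lizard tails,
    obtained non-lethally by autotomy, as the biomonitor tissue. From tidy
    concentration tables of tail, putative-prey and soil samples the package
    computes site-level Bioaccumulation Factors (BAF), Trophic Transfer
    Factors (TTF) and the Hakanson Potential Ecological Risk index (RI) with
    its risk classification, summarises stomach-content diet composition
    (frequency of occurrence and percentage contribution by mass), runs a
    site-comparison statistical battery, and simulates site-structured
    lognormal concentration data for validation. Ships a coastal Atacama
    Desert survey (sites PAZ, PAL, CAL) as a bundled fixture dataset and can
    regenerate its index tables in one call.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
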