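Package: triplerad
Title: Design, Simulation and Demultiplexing of 2RAD/3RAD Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for dual- and triple-enzyme restriction-site associated
    DNA sequencing (2RAD/3RAD). Provides a restriction-enzyme registry with
    IUPAC motif search and double/triple digestion of linear or circular
    sequences, regeneration and validation of the quadruple-indexed adapter
    designs (including the third-enzyme adapter-dimer blocking logic), a
    seeded stochastic simulator of digestion-ligation cycling, PCR, size
    selection and four-stream read generation, and a demultiplexer with
    cut-site remnant checking, third-enzyme locus quantification and
    molecular-ID-tag (8N) PCR-duplicate removal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
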