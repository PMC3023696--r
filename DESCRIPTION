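Package: rnasketch
Title: Consensus RNA Secondary-Structure Diagrams from Annotated Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Draws publication-style consensus (and single-sequence) RNA
    secondary-structure diagrams from Stockholm multiple-sequence alignments.
    Reads alignments carrying a consensus structure line (matched angle
    brackets), a column-label line and layout commands; computes
    Gerstein-Sonnhammer-Chothia sequence weights, per-column conservation
    tiers and per-pair covariation classes; lays the molecule out with
    strictly constant backbone spacing, loops on circles solved by binary
    search and multistem junctions solved as small constrained non-linear
    programs; and writes SVG. Includes a seeded generator of tiny synthetic
    annotated alignments for tests and demos.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    jsonlite,
    nloptr,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    xml2
Suggests:
    ape,
    ggplot2,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
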