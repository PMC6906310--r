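Package: ivoryid
Title: Species Identification of Elephantid Ivory from Short Cytochrome b Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An in-silico toolkit for molecular identification of elephantid
    ivory from a 116 bp cytochrome b fragment. Simulates PCR with the
    degenerate elephantid-universal primer pair L15123/H15240 (IUPAC-aware
    mismatch accounting with a 3'-end rule), reconstructs a clade-structured
    reference haplotype panel for Asian elephant, African savanna elephant
    (S clade), the Loxodonta F clade and woolly mammoth, computes
    transitions-only p and Kimura 2-parameter distances with barcoding-gap
    summaries, neighbour-joining trees and monophyly checks, assigns
    fragments to species/clade by diagnostic nucleotides and by distance to
    the panel with forensic conflict reporting, and provides an ancient-DNA
    cytosine-deamination simulator plus copy-number arithmetic for
    sensitivity-style experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
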