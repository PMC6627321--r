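Package: utrscape
Title: Comparative Feature Analysis of 5' Untranslated Regions in Ortholog Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of spliced 5' untranslated regions
    (5'UTRs) across vertebrate ortholog families. Scores multiple-alignment
    columns for identity and occupancy and calls conservation hot spots;
    censuses upstream start and stop codons by intron-delimited section; finds
    upstream open reading frames (uORFs), their geometry relative to the main
    ORF, and the strength of their Kozak start-codon contexts; profiles GC
    content and base-repetition-rich subregions; enumerates hairpin loops from
    dot-bracket secondary structures; and measures variant overlap with hot
    spots, with group-wise section-length comparisons (Mann-Whitney,
    Bonferroni). A seeded synthetic-family generator with recorded ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    generics,
    Biostrings,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
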