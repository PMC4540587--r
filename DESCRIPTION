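Package: retroils
Title: Incomplete Lineage Sorting from Retrotransposon Presence/Absence Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies incomplete lineage sorting (ILS) across rapid
    radiations from retrotransposon presence/absence markers. Maps binary
    insertion characters onto rooted species trees under Felsenstein's
    polymorphism parsimony (and plain Dollo parsimony), infers per-marker ILS
    duration and per-branch ILS levels and insertion rates, enumerates the
    combinatorics of hemiplasy under stochastic sorting of a biallelic
    polymorphism, tests alternative placements of a focal taxon for
    hybridization-like asymmetry, summarises target-site-duplication motifs,
    and simulates marker matrices under the multispecies coalescent with known
    per-locus truth. Reads and writes presence/absence matrices in wide CSV,
    discrete PHYLIP and NEXUS standard formats, and rooted trees in Newick.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
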