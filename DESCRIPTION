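Package: nitribalance
Title: Abundance Balance of Nitrifier Guilds in Marine Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs absolute abundances of ammonia-oxidizing archaea
    (AOA) and nitrite-oxidizing bacteria (NOB) in marine sediment cores from
    16S rRNA amplicon OTU tables and qPCR totals, compares observed AOA:NOB
    cell-abundance ratios in oxic sediment layers against a trait-based
    theoretical band derived from biomass yields and cell carbon quotas, and
    quantifies how reattributing a candidate NOB lineage to the
    nitrite-oxidizer guild changes the ratio statistics. Includes oxygen
    penetration depth inference from porewater profiles, trapezoidal
    depth-averaged lineage composition, identity-based linking of genome 16S
    sequences to amplicon OTUs, occurrence screening of read sets against a
    query 16S sequence, and a synthetic sediment-core generator that makes the
    whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
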