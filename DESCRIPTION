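Package: secretome
Title: Secretome Profiling and Aggregate-Forming Protein Screening for
    Granular Metaproteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for extracellular metaproteomes of granular
    microbial enrichments. Provides in-silico proteolysis for four protease
    regimes and iBAQ conversion via theoretical peptide counts, merging of
    approach-specific protein groups into experiment-wide groups under a
    pairwise consistency rule, physicochemical property calculation (GRAVY,
    aromaticity, net charge, cysteine fraction, length) and per-residue
    structural aggregation (beta-sheet fraction, relative surface
    accessibility, disorder), biomass accounting by secretion evidence,
    subcellular location, taxonomy and COG category, and a rank-percentile
    screen with complete-linkage clustering that nominates candidate
    aggregate-forming extracellular proteins. A synthetic metaproteome
    generator with planted ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
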