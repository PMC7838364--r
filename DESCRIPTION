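Package: oilnet
Title: Cross-Species Co-Expression Networks for Seed Oil Biosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-transcriptomics toolkit linking interspecific
    variation in seed-oil fatty-acid unsaturation to expression shifts of
    duplicated desaturase genes. Implements fatty-acid profile statistics
    (omega-6/omega-3 desaturation efficiencies, saturation ratios, qPCR
    relative expression), expression-matrix processing (FPKM normalisation,
    transcript-cluster collapsing, permutation differential-expression
    screening, profile clustering, CV stability ranking), weighted gene
    co-expression network construction from first principles (soft-threshold
    adjacency, topological overlap, tree cutting, module eigengenes),
    oil-module selection with permutation and hypergeometric validation,
    reciprocal-best-hit orthology and orthogroup clustering, cross-species
    conserved co-expression detection, and pathway expression-stoichiometry
    comparison. Ships a synthetic multi-species time-course generator so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
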