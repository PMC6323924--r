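Package: kinconform
Title: Kinase Conformation Classification from Geometric Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies protein kinase structures into the five
    pharmacologically relevant conformations (CIDI, CIDO, CODI, CODO, wCD)
    defined by the DFG motif and alphaC-helix. Provides PDB parsing and
    motif location for single kinase domains, an eight-dimensional geometric
    descriptor set with (-1, 1) normalization, a two-stage random-forest
    classifier (DFG stage, then alphaC stage) with proximity-based
    missing-data imputation, descriptor-space similarity search, and a
    ligand-fragment enrichment pipeline that associates chemical
    substructures with conformations via one-sided Fisher's exact tests
    under Bonferroni control. Includes generators for synthetic toy kinase
    structures, labeled descriptor datasets, and ligand corpora with planted
    enriched substructures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
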