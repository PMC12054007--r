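Package: hdrascan
Title: Domain-Architecture Classification and Gene-Cluster Function Inference
    for Soluble Heterodisulfide Reductase Subunit A (HdrA)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies HdrA proteins of methane- and alkane-metabolizing
    archaea into 28 architecture classes and 4 major types from motif-derived
    domain architectures, calls the FAD-stabilizing residues that mark
    flavin-based electron bifurcation (FBEB) competence and the molybdopterin
    oxidoreductase active-site state, prepares conserved core regions for
    phylogenetics (identity clustering, type II splitting, GltD excision,
    alignment-column entropy trimming), detects hdrA-containing gene clusters
    in genome neighborhoods, and infers candidate FBEB/FBEC reactions from
    cluster composition. Ships a synthetic-data generator with known ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
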