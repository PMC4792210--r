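Package: dsa7tm
Title: Distance Scoring Analysis of Seven-Transmembrane Helix Bundles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the conservation of Calpha-Calpha distances across an
    ensemble of aligned protein structures as the inverse of the coefficient
    of variation (mean distance divided by its standard deviation), the
    distance scoring analysis (DSA) used to compare seven-transmembrane
    (7TM) helix bundles of microbial rhodopsins and G protein-coupled
    receptors. Provides a family-wide common residue numbering scheme
    anchored at the most conserved position of each helix (the *.50
    convention), extraction of fixed-length Calpha bundles from PDB/mmCIF
    files, Kabsch superposition RMSD and distance-vector correlation
    matrices, per-column conservation profiling of multiple sequence
    alignments, ranked-pair cumulative-ratio curves, and a synthetic
    7TM-bundle generator so that the full pipeline is testable without
    downloading any structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
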