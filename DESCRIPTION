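Package: crossdockr
Title: Cross-Docking Harness with Symmetry-Aware Pose Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Runs cross-docking studies over a family of pre-aligned
    receptor/ligand co-crystal structures: every ligand is docked into every
    receptor through a pluggable docking engine (an AutoDock Vina adapter and
    a deterministic mock engine are provided), each pose is scored by
    in-place, symmetry-corrected heavy-atom RMSD against its crystal
    reference, and the ligand-by-receptor matrices, per-receptor averages,
    success counts and receptor rankings used for ensemble structure
    selection are assembled and written as spreadsheet and CSV reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
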