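Package: kascade
Title: Cascade Support Vector Machines for Lysine Acetylation Site
    Prediction and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts lysine acetylation sites in protein sequences from
    19-residue peptide windows encoded with physicochemical properties,
    position-specific scoring matrices, auto-covariation, residue
    composition, secondary structure and accessible surface area. Handles
    the roughly 10:1 negative-to-positive class imbalance with a cascade
    of balanced radial-basis SVM layers whose thresholds retain 95% of
    positives per layer while iteratively pruning confidently negative
    samples. Includes two-step mRMR plus incremental feature selection
    maximising validation Matthews correlation, descriptive positive
    versus negative site statistics (per-position property profiles,
    information entropy, composition bias, secondary-structure and
    surface-area distributions), and a deterministic synthetic-data
    generator so the whole pipeline is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
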