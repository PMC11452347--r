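Package: vasctalk
Title: Ligand-Receptor Co-Expression Analysis for Regional Brain Vasculature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers cell-cell communication between capillary endothelial
    cells and perivascular cell types (pericytes, astrocytes, fibroblasts,
    tanycytes) from single-cell RNA-seq counts of two brain regions.
    Provides quality-control filtering with a library-complexity (novelty)
    gate, log-normalization to 10,000 transcripts per cell, Wilcoxon
    rank-sum differential expression with detection and fold-change gates,
    assembly of a ligand-receptor database supplemented with differentially
    expressed genes gated by subcellular localization and experimentally
    validated protein-protein interaction partners, co-expression
    interaction scores with a bootstrap-calibrated significance cutoff
    (one-sided empirical p, Bonferroni-corrected), exclusion of
    non-specific pericyte pairs, and per-region summary counts. A synthetic
    data generator with planted ground truth emulates the two-region
    vascular study design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
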