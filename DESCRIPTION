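Package: coexpair
Title: Non-Linear Gene-Pair Interaction Screening and Consensus
    Co-Expression Networks for Binary Disease Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening pairwise non-linear (product-term)
    interactions between transcript expression levels and a binary disease
    outcome. Implements single-gene and gene-pair logistic screens with
    interaction classification, matched case-control resampling with
    conditional logistic regression and stability summaries, conditional
    odds-ratio curves and log-odds surfaces for interacting pairs, consensus
    co-expression networks built from subsampled Renyi mutual information
    graphs with data-processing-inequality pruning, and deterministic
    k-shortest-path discovery of relay transcripts between candidate genes,
    together with synthetic cohort and count-matrix generators with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
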