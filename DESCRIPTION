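Package: pimotif
Title: Pairwise Interaction Models of Transcription Factor Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maximum-entropy sequence models of transcription factor binding
    sites with single-nucleotide fields and pairwise couplings between
    positions (pairwise interaction models, PIMs), fitted by exact
    marginal-matching gradient descent with greedy, BIC-controlled addition
    of couplings. Includes the self-consistent binding-site refinement
    workflow on ChIP fragment sequences (scan, 50% true-positive-rate
    cutoff, relearn, iterate), PWM and PWM-mixture baselines (Hamming
    K-means), energy-landscape analysis (local minima and basins of
    attraction), direct and mutual information between positions,
    participation ratios, spectral (Hopfield-pattern) decomposition of the
    coupling matrix, and a synthetic-data generator with planted sites for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    withr,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
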