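Package: tradescape
Title: Morpho-Functional Trade-Off Landscapes for Landmark Shape Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to relate landmark-based cranial shape to competing
    functional demands through performance-surface modelling. Provides
    generalized Procrustes alignment, principal-component morphospaces and
    theoretical shape grids; polynomial, thin-plate-spline and kriging
    performance surfaces selected by k-fold cross-validation; maximum
    likelihood estimation of the trade-off weight w that mixes two
    performance surfaces into a combined functional landscape;
    sliding-window comparison of theoretical "w volume" against observed
    morphological disparity with model-based clustering; two-block partial
    least squares with major-axis shape prediction for cross-clade
    transfer; phylogenetic comparative utilities (BM/OU/EB model fitting
    with AICc, PGLS with permutation tests, independent contrasts,
    phylogenetic PCA, Mantel tests, rate-table associations); and a
    synthetic-study generator with brute-force oracles for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    mclust,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
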