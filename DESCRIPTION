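Package: interlink
Title: Patient-Similarity Graph Semi-Supervised Learning with
    miRNA-Target Inter-Relations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph-based semi-supervised prediction of binary clinical
    outcome from coupled miRNA and gene expression profiles.  Builds
    Gaussian k-nearest-neighbour patient-similarity graphs from a single
    expression layer, reconstructs a second patient graph from known
    miRNA to target-gene relations by summing expression products over
    target pairs, fuses graphs by optimising Laplacian combination
    coefficients under a budget constraint, and solves the regularised
    harmonic label-propagation problem in closed form.  Includes a
    synthetic cohort generator with planted repression-type miRNA-target
    signal, random edge-damage experiments with cross-validated AUC and
    Wilcoxon signed-rank comparisons, leave-one-feature-out AUC
    importance, and five alternative inter-relation similarity measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
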