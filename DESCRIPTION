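Package: fluorseq
Title: Simulation and Classification of Single-Molecule Protein
    Fluorosequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for single-molecule protein fluorosequencing data
    analysis. Digests a reference proteome in silico, converts labeled
    peptides into dye sequences, and simulates fluorosequencing dye
    tracks and raw intensity reads under an explicit error model
    (missing fluorophores, photobleaching, Edman cycle failure, peptide
    detachment, Gaussian radiometry noise). Classifies raw reads against
    the reference with a reduced-state hidden Markov model Bayesian
    classifier using factored sparse transition operators and emission
    pruning, with a KD-tree k-nearest-neighbor classifier over
    deduplicated dye tracks, and with a two-stage hybrid classifier that
    rescores a kNN shortlist by truncated Bayes. Includes
    precision-recall and score-calibration evaluation, peptide and
    protein roll-up inference, and designed-simulation estimators that
    recover the sequencing error rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
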