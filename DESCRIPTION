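Package: slmcnv
Title: Shifting Level Models for Copy-Number Segmentation of Genomic Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation of noisy, spatially ordered genomic signals (window
    read counts or log2-ratios) for copy-number variant detection using
    shifting level models: a piecewise-constant latent mean observed through
    Gaussian noise, decoded as a hidden Markov model by Viterbi dynamic
    programming. Includes the homogeneous model (SLM) for dense
    whole-genome profiles, the heterogeneous model (HSLM) whose jump
    probability grows with the genomic distance between adjacent windows
    (for sparse exome-like data), GC-content and mappability read-count
    normalization, a synthetic-profile simulator, breakpoint and CNV
    evaluation metrics (ROC/AUC, breakpoint-distance, size-stratified
    precision/recall), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
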