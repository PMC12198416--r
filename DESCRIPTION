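Package: readoutbias
Title: Dissecting Encoding and Readout of Sequential Evidence with
    Intersection Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for studying selective
    (confirmation-biased) processing of sequential sensory evidence.
    Generates trials of a sequential evidence estimation task (12 angular
    samples per trial around a hidden generative mean, with an intermittent
    categorical choice or a 75 percent valid cue), simulates ideal and
    biased observers, and simulates neural population activity with a
    linear encoding/readout model. Provides bias-corrected discrete
    information measures - mutual information and conditional mutual
    information on equipopulated bins, shuffle-based limited-sampling
    corrections, trial-count matching - and intersection information
    II(S;R;E) via constrained maximization over joint distributions with
    fixed target-linked pairwise marginals. Includes psychophysical-kernel
    analyses, time-resolved neural information pipelines with PCA
    dimensionality reduction, cross-validated linear decoding, and an
    inference layer with cluster-based and spin-rotation permutation tests,
    FDR correction, Bayes factors, and repeated-measures ANOVA effect
    sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
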