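Package: rotscan
Title: Discriminative Hidden Markov Modelling of Mental-Rotation Scanpaths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for classifying mental-rotation strategies from
    eye-movement scanpaths. Fixation tables are coded over four areas of
    interest (the upper and lower arms of the two block figures) into
    per-fixation feature sequences (log fixation duration, log saccade
    length, AOI identity, four-category saccade direction). A block-structured
    hidden Markov model with class-specific hidden-state subsets is trained
    generatively by Baum-Welch and refined by conditional-likelihood
    (discriminative) gradient ascent, then used to segment scanpaths into
    cognitive processing states and to classify trials into the two instructed
    rotation strategies. Logistic-regression and support-vector baselines,
    repeated stratified cross-validation, confusion-matrix accounting,
    hidden-state-count selection, and a synthetic-data generator parameterized
    by published model estimates round out the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    mgcv,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
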