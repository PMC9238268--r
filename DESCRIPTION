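Package: ramanoid
Title: Raman Microspectroscopy Classification of Organoid Differentiation States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying the differentiation state of unlabeled
    organoids from confocal Raman point spectra. Implements the full analysis
    chain: spectral post-processing (cosmic-ray despiking, Savitzky-Golay
    denoising, iterative polynomial fluorescence-background removal,
    phenylalanine-peak normalization, and rejection of Matrigel-contaminated
    spectra), diagnostic peak-intensity statistics (one-way ANOVA with
    Dunnett's post hoc and Bonferroni-corrected pairwise t-tests), singular
    value decomposition scatter analysis with a perpendicular-bisector
    separation statistic, robust (ramp-loss) support vector machine
    classification over repeated stratified splits, and two blinded-assignment
    procedures (peak-wise majority vote and SVD codistribution). A synthetic
    spectrum generator with class-specific peak profiles, fluorescence
    background, noise, spikes, and Matrigel contamination makes every stage
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    multcomp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
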