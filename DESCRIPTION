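Package: ebmseq
Title: Event-Based Modelling of Biomarker Abnormality Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits event-based models (EBM) of disease progression to
    cross-sectional biomarker tables: covariate adjustment of regional
    brain volumes against a control cohort, biomarker selection by
    Bonferroni-corrected group tests, two-component kernel-density
    mixture models yielding per-subject event likelihoods,
    maximum-likelihood event-sequence inference by multiply initialized
    greedy ascent with Metropolis MCMC posterior sampling over
    permutations, positional variance diagrams, maximum-likelihood
    patient staging, and the associated validation machinery (bootstrap
    and repeated stratified k-fold re-estimation of the sequence,
    longitudinal staging consistency, stage-outcome association). A
    synthetic-cohort generator with known ground-truth ordering and
    latent stages supports testing and calibration without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
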