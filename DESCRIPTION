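Package: bradyemg
Title: Quantifying Bradykinesia from Surface EMG Burst Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for quantifying bradykinesia, the cardinal
    Parkinsonian slowing of voluntary movement, from forearm surface
    electromyography recorded during repetitive motor tasks (finger tapping,
    hand open-close). Implements linear-envelope preprocessing (DC-offset
    removal, zero-phase Butterworth band-pass, edge trimming, rectification,
    low-pass envelope), prominence-based detection of muscle-activation
    bursts with three burst metrics (peak count, median peak amplitude, mean
    inter-peak interval), a windowed time-domain feature bank (Hudgins and Du
    sets plus MAV1, MAV2, approximate and sample entropy),
    leave-one-subject-out random-forest regression of MDS-UPDRS III motor
    scores, mixed-design 2x2 ANOVA and post-hoc statistics with Bonferroni
    adjustment, exact-permutation Spearman correlations for small samples,
    and a synthetic cohort generator producing burst-modulated band-limited
    noise with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    randomForest,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
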