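Package: conndyn
Title: Dynamic Cortical Connectivity States from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for dynamic functional connectivity in
    multichannel scalp EEG recorded during anesthetic maintenance.
    Estimates surrogate-corrected weighted phase lag index (wPLI) spectra
    with the multitaper method over sliding windows, discovers recurring
    connectivity states by PCA and k-means clustering with a split-half
    stability index, quantifies per-subject state dynamics (occurrence
    rates, Markov transition probabilities, global transition probability),
    and provides the cohort statistics layer (normality-routed correlations,
    Bonferroni and Benjamini-Hochberg corrections, covariate-adjusted
    regression with age-adjusted MAC). Includes a synthetic cohort
    generator with planted connectivity states and age effects that serves
    as ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
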