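Package: iedclust
Title: Unsupervised Classification of Interictal Epileptiform Discharges
    and Inter-Rater Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated classification of interictal epileptiform discharges
    (IEDs, epileptic spikes) on multichannel EEG: band-pass filtering and
    resampling, global-field-power peak alignment, epoching, meta-IED
    construction across channels of interest, wavelet feature extraction with
    deviation-from-normality feature selection, and superparamagnetic (Potts
    model) clustering with automatic class-count selection and non-IED
    rejection. Includes a validation framework for comparing automated and
    human classifications: counts-weighted variation of information with a
    surrogate-observer null model and non-parametric bootstrap, Bhattacharyya
    histogram overlap of pooled agreement distributions, majority-vote silver
    standard, sensitivity and specificity, Cohen's kappa, and classification
    overlap matrices. Reads and writes BrainVision and EDF recordings, CSV
    event markers and TSV label files, and ships a synthetic EEG generator
    with known spike classes and simulated imperfect observers so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    nortest,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
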