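Package: crcnotes
Title: Colorectal-Cancer Risk Models from Primary-Care Notes and Codes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for assessing the added
    predictive value of free-text general-practice consultation notes in the
    early detection of colorectal cancer. Provides a seeded synthetic
    electronic-medical-record generator (ICPC-coded consultations with short
    noisy Dutch-like notes), patient labelling and two-year observation-window
    extraction with a five-month pre-diagnosis exclusion gap, skip-gram
    negative-sampling word embeddings trained from scratch (with bigram
    phrasing and frequency subsampling), embed-and-aggregate patient
    representations, three logistic risk models (structured features, text
    embeddings, and both) trained by Adam on binary cross-entropy with early
    stopping, and a paired percentile-bootstrap evaluation protocol covering
    AUROC, AUPRC, specificity at a sensitivity floor, Brier (skill) scores and
    LOWESS calibration curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Rcpp,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
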