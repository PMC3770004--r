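Package: scvoice
Title: Voice-Based Sasang Constitution Diagnosis with Frame-Level
    Gaussian Mixture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Text-dependent diagnosis of Sasang constitution types (Tae-Eum,
    So-Eum, So-Yang) from sentence voice recordings. Each recording is reduced
    to a sequence of 13-dimensional frame feature vectors (12 mel-frequency
    cepstral coefficients plus the frame's relative time position), features
    are age-standardized with a moving +/- 5-year window, and one 15-component
    Gaussian mixture model per gender and constitution class is trained by
    expectation-maximization with a time-partition initialization. Recordings
    are classified by maximum normalized likelihood, and diagnostic stability
    is quantified by a repeated-measurement protocol (majority-decision
    repeatability and the mean and standard deviation of the decision
    confidence). Includes a synthetic cohort generator, at both the
    frame-feature and waveform level, so the full pipeline is testable without
    clinical recordings, and a command-line interface for the train, classify,
    evaluate and simulate workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
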