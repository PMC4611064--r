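Package: fbcsp
Title: Filter-Bank Common Spatial Patterns for Subject-Independent EEG
    Classification and Neurofeedback Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-class EEG pattern classification built on filter-bank Common
    Spatial Patterns (FBCSP): a Chebyshev type-2 band-pass filter bank,
    per-band CSP spatial filtering with log-variance features,
    mutual-information feature selection, and a soft-margin linear support
    vector machine.  Supports fusion of multiple subjects' recordings into a
    single subject-independent model, offline evaluation (repeated stratified
    cross-validation, label-permutation significance testing,
    leave-one-subject-out transfer), a simulated closed-loop neurofeedback
    session with thermometer feedback, CSP pattern similarity analysis, and a
    ground-truth synthetic EEG generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
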