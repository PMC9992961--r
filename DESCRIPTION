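Package: mifusion
Title: Dual-Branch Convolutional Fusion Decoding of Single Upper-Limb
    Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("Rikard", "Engstrom", email = "r.engstrom@example.org",
           role = c("aut", "cre"))
Description: Tools for decoding single upper-limb motor-imagery tasks from
    epoched multichannel EEG. Implements the full decoding chain: an
    event-related desynchronization (ERD) structured synthetic EEG generator,
    sensorimotor channel selection with 8-30 Hz zero-phase band-pass
    filtering and decimation to 250 Hz, one-vs-rest common spatial patterns
    (CSP), Morlet continuous-wavelet scalogram images of CSP virtual
    channels, a raw-signal convolutional branch and a VGG16-style
    time-frequency image branch trained with Adam, feature-level fusion of
    the two penultimate layers into a linear support-vector machine, and
    stratified five-fold cross-validation with accuracy, Cohen's kappa,
    confusion matrices and paired t-test comparisons, including a classical
    CSP log-variance baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
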