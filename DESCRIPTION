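Package: tactrej
Title: Reject-Option Motion Classification for Tactile-Sensor Prosthetic Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-driven pipeline for classifying wrist-hand motions from
    two-channel piezoelectric (PVDF) forearm tactile recordings, with three
    reject-option mechanisms that withhold unreliable decisions: one-class SVM
    outlier rejection, entropy-based rejection on a softmax multilayer
    perceptron, and a parameter-free one-vs-rest sign-consistency check
    (OvR-RO). Includes a seeded synthetic-recording simulator that emulates the
    experimental protocol (cued trials, motion-specific biphasic transients,
    noise, drift and power-line interference), digital conditioning and
    threshold-based onset detection, windowed feature extraction, classifier
    training with fixed hyperparameters, and a session-wise evaluation
    framework (accuracy on accepted trials, category-wise rejection rates,
    rejection precision, paired t-tests with Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    signal,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
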