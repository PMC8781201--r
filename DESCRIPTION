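Package: passivebci
Title: Online-Compatible EEG Classification of Mental Workload and
    Affective State with Instance-Weighted Transfer Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for simultaneous decoding of mental workload (easy
    versus difficult arithmetic) and affective state (relaxed versus
    stressed) from multi-channel EEG in a passive brain-computer
    interface setting.  Provides a synthetic multi-subject EEG session
    generator with controllable state effects and inter-subject domain
    shift, causal preprocessing (band-pass filtering, polyphase
    resampling, artifact subspace reconstruction), band-power features
    from Hilbert envelopes in bands anchored to the individual alpha
    frequency, shrinkage-regularized linear discriminant analysis,
    condition-stratified majority-vote ensembles, the InstanceEasyTL
    instance-reweighting transfer-learning algorithm for cross-subject
    decoding, and a chronological online simulator with exact binomial
    chance thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
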