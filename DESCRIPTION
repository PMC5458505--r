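Package: ctcoord
Title: Detection and Coordination Analysis of Sleep Downstates and Spindles
    in Cortico-Thalamic Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing simultaneous cortical and thalamic bipolar
    depth recordings during non-REM sleep. Detects slow-oscillation
    downstates from zero crossings of the 0.1-4 Hz filtered signal with
    amplitude-percentile selection and high-gamma based polarity
    assignment; detects sleep spindles either by an envelope-threshold
    rule or by a two-step candidate-epoch plus per-channel logistic
    regression classifier with collinearity pruning, stepwise AIC model
    selection, bootstrap stability analysis and cross-validated
    probability thresholding; and quantifies the temporal coordination of
    downstates and spindles within and between structures via peri-event
    histograms, binomial order tests, conditional probabilities, delay
    estimators, enrichment factors and coupling proportions. A synthetic
    multichannel generator with scheduled, coupled events and 1/f
    background provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    stats,
    graphics,
    utils
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
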