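Package: scalphfo
Title: Detection and Phenotypic Clustering of Scalp High-Frequency Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for scalp high-frequency
    oscillations (HFOs, 80-250 Hz ripples) in absence-epilepsy EEG. Implements
    a two-stage Hilbert-envelope detector on average-montage scalp recordings,
    morphological characterisation of each event (average frequency, duration,
    amplitude z-score, number of cycles), k-means phenotyping with elbow-based
    model selection, and epoch-association statistics (chi-square test,
    multinomial logistic regression, Tukey-Kramer HSD, and age-adjusted linear
    regression). A synthetic-data module simulates annotated scalp EEG scenes
    (pink-noise background, spike-wave discharge trains, spikes with
    superimposed ripple bursts) and feature-space mixtures so that every stage
    can be exercised and validated without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    nnet,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
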