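Package: somnus
Title: Spiking-Network Reinforcement Learning with Sleep Replay
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates a three-layer network of map-based (Rulkov) spiking
    neurons that learns complementary foraging tasks in a grid world through
    rewarded spike-timing-dependent plasticity. Provides protocols for
    sequential, interleaved and sleep-interleaved training, a REM-like sleep
    phase with rate-matched Poisson replay, and an analysis suite for the
    synaptic weight space: receptive fields, a particle responsiveness
    metric, SVM classification of weight configurations, PCA/kernel-PCA
    trajectories, solution-manifold distances and 2-D weight histograms.
    The package reproduces catastrophic forgetting under sequential task
    training and its mitigation by interleaved sleep at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    kernlab
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
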