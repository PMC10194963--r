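Package: rivalinfo
Title: Information Dynamics of Bistable Perception from EEG and Optokinetic Nystagmus
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for no-report bistable perception experiments.
    Infers perceptual switches from optokinetic-nystagmus (OKN) eye signals
    (slow-phase velocity extraction, zero-crossing detection, and a 1-D
    convolutional network decoder), quantifies delay-resolved directed
    information between EEG regions of interest with a Gaussian-copula
    conditional mutual information estimator, measures compression-based
    signal differentiation (Kolmogorov complexity upper bounds via DEFLATE),
    computes Morlet time-frequency power with decibel baseline
    normalization, and assesses condition contrasts with cluster-based
    permutation statistics.  Ships a ground-truthed synthetic-session
    generator emulating gamma-distributed percept dominance durations, OKN
    traces with blink and fast-phase artifacts, and multichannel EEG with
    lagged anterior-to-posterior coupling and low-frequency power
    modulation, so the full pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    fitdistrplus,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
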