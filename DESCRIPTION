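Package: thetadyn
Title: Spectral, Coupling and Coherence Analysis of Hippocampal-Prefrontal Local Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing multi-lead local field potential
    recordings from delayed-alternation sessions: 60 Hz notch filtering,
    short-time spectral decomposition (1000 ms windows, 200 ms overlap),
    normalized session power spectra and theta/delta ratios, running-speed
    coupling of band power, phase-amplitude coupling via the entropy-based
    modulation index and comodulograms, inter-area magnitude-squared
    coherence with per-trial delay-period summaries and error/correct
    difference scores, and a four-class "spectral phenotype" decoding
    protocol (training-size sweeps, shuffled nulls, grouped leave-one-out
    designs). A synthetic cohort generator plants every analysed effect
    (delta/theta balance, speed coupling, cross-frequency coupling,
    outcome-dependent inter-area coherence, group-by-delay accuracy) with
    named parameters so each stage is verifiable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
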