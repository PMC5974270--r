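Package: nocidecode
Title: Decoding the Intensity and Onset of Acute Pain from Simulated
    Cortical LFP and Spike Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for decoding acute pain
    intensity and onset from multi-channel local field potentials (LFP)
    and spike trains, modeled on anterior cingulate cortex tetrode
    recordings around noxious laser stimulation. Provides a seeded
    synthetic session generator (pink-noise LFP with band-limited
    event-related synchronization, Poisson units, withdrawal latencies),
    multitaper spectral estimation with Slepian tapers, baseline-referenced
    band-power z-scores, cumulative 50-ms spike-count and sliding-window
    LFP band-power features, cross-validated polynomial-kernel SVM
    decoding trajectories with permutation chance levels, and
    threshold-fraction (1/e) onset estimation compared against withdrawal
    latency.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
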