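Package: eegagree
Title: Wet Versus Dry EEG Agreement Analysis on Simulated Oddball and
    Resting-State Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates paired wet- and dry-electrode multichannel EEG
    sessions (auditory oddball task and eyes-open rest) with known ground
    truth, preprocesses them (mastoid re-referencing, bad-channel
    interpolation, band-pass filtering, epoching, resampling, ICA-based
    ocular artifact removal, peak-to-peak trial rejection), extracts
    mismatch-negativity amplitude and latency, theta-band event-related
    power via Morlet wavelets, plus-minus signal-to-noise ratios, and
    sensor-level resting-state connectivity (phase lag index and minimum
    spanning tree diameter), and quantifies between-system agreement with
    Bland-Altman statistics, repeated-measures ANOVA, paired t-tests and
    Wilcoxon signed-rank tests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
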