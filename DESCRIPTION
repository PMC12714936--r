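Package: abrnirs
Title: Auditory Evoked Responses from Simultaneous EEG and fNIRS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of auditory evoked responses recorded simultaneously
    with EEG and functional near-infrared spectroscopy (fNIRS). Builds click
    and block-design "warble" stimulation protocols with dB-SPL drive-voltage
    calibration, simulates seeded EEG auditory brainstem responses (Jewett
    waves I/III/V) and fNIRS hemodynamics with known ground truth, reads and
    writes EDF and SNIRF recordings, scores ABR waves (latencies, amplitudes,
    inter-peak intervals, SNR) from band-passed epoch averages, and runs a
    block-design statistical battery: grand averaging, PCA of epoched
    responses, task GLM with Benjamini-Hochberg correction, time-locked
    cross-correlation, stimulation-versus-silence contrasts, and a spatial
    repeated-measures ANOVA with Holm-corrected post-hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    rhdf5,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
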