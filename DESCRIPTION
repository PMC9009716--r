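Package: gawmode
Title: Cycle-Based Glottal Area Waveform Analysis and Vibratory Mode
    Change Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of glottal area waveforms (GAWs) extracted from
    high-speed videoendoscopy of the larynx. Provides maximum-based
    oscillation cycle detection with prominence and minimum-distance
    filtering, damaged-frame and outlier-cycle exclusion, seven
    cycle-based vibratory parameters (local fundamental frequency,
    dynamic range, left-right phase asymmetry, amplitude and time
    periodicity, open and closing duration), detection and
    characterization of spontaneous vibratory mode changes (sustained
    jumps or drops of local fundamental frequency), and aggregation of
    results over a grid of laryngeal nerve stimulation conditions.
    Includes a phenomenological synthetic phonation generator so that
    the whole pipeline can be exercised and validated without video
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
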