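Package: chronrig
Title: Timing-Accurate Stimulus Calibration and Event-Aligned Spike
    Analysis for Behavioral Neurophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for the computational side of a temporally precise
    rodent-behavior rig. Simulates event-locked spiking under event-timing
    noise and quantifies the resulting degradation of peri-event time
    histograms and spike/event mutual information; runs closed-loop sound
    pressure level (dB SPL) calibration of pure tones and white noise
    against a pluggable transducer backend and synthesizes equalized
    waveforms; characterizes and compensates command-to-actuation delivery
    latencies. Includes a command-line interface, delimited-text timestamp
    I/O, JSON reports and 16-bit PCM WAV output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
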