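Package: fatiguelab
Title: Physiology-Driven Mental Fatigue Labeling for Driver Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assess driver mental fatigue from wearable physiology.
    Computes the EEG-derived MDrow drowsiness index (parietal strict-alpha
    global field power normalized to an eyes-closed rest maximum), detects
    eyeblinks on a single frontal channel (rate, duration, amplitude),
    extracts heart rate and Lomb-Scargle frequency-domain heart rate
    variability from photoplethysmography, and labels low/high-fatigue
    periods of a monotonous driving task by either the individual EEG index
    or time-on-task. A synthetic-data generator with known ground truth
    (fatigue trajectory, blink events, inter-beat intervals) supports
    end-to-end validation, and a paired effect-size harness quantifies
    which labeling approach yields larger low-vs-high contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
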