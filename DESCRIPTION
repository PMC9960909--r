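Package: ventasync
Title: Patient-Ventilator Asynchrony Detection from Ventilator Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects patient-ventilator asynchrony (PVA) in airway pressure,
    flow and volume waveforms sampled from mechanical ventilators. Segments
    waveform streams into breaths by flow-threshold crossing, applies
    rule-based detectors for double triggering (expiratory time shorter than
    half the rolling mean inspiratory time, or volume failing to return to
    baseline) and ineffective triggering (rise-then-fall expiratory flow
    deflections found via the derivative of the smoothed flow curve), computes
    a sliding-window asynchrony index with severe-asynchrony alarming, and
    evaluates detector output against gold-standard annotations with
    sensitivity, specificity, PPV and NPV. A single-compartment
    respiratory-mechanics simulator generates labelled synthetic waveforms
    with injected asynchrony events so the whole pipeline can be exercised and
    benchmarked without patient data. All results are tibbles that compose
    with the pipe; ggplot2 autoplot() methods and broom-style tidy()/glance()
    methods are provided, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
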