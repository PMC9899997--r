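Package: cvrmap
Title: Multi-Channel NIRS Cerebrovascular Reactivity Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for continuous cerebrovascular reactivity (CVR) mapping
    from multi-channel near-infrared spectroscopy (NIRS) and non-invasive
    arterial blood pressure (niABP) recordings. Reads dual-rate time-series
    exports, aligns the streams with a fixed inter-device delay, removes scalp
    contamination by short-channel subtraction, decimates every trace with
    non-overlapping 10-s moving averages to isolate slow vasogenic waves, and
    computes sliding-window Pearson correlation indices (HbOx, HHbx, tHbx,
    HbDiffx, COx) between each hemoglobin surrogate and niABP. Indices are
    rendered as timed heat-map frames on a 2D brain template with a diverging
    blue-to-red colour map. A physiologically structured signal simulator with
    a known autoregulation coupling parameter replaces the acquisition
    hardware, so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
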