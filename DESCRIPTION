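Package: optopace
Title: Analysis of Optogenetically Paced ECG, Vessel Videometry, and
    Cardiac-Gated Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of intravital cardiovascular optogenetics
    experiments. Classifies optically paced heartbeats from ECG recordings by
    stimulus latency windows and measures R-wave durations and PR intervals by
    zero-crossing interpolation; tracks vessel diameter from brightfield video
    by frame stabilization, band-averaged intensity profiles, and sub-pixel
    dual-peak sidewall detection, with dilation response metrics; performs
    retrospective cardiac- and respiratory-gated reconstruction of line-scanned
    fluorescence microscopy; and analyzes pacing-coupled calcium-indicator
    transients. Includes seeded synthetic-data generators with exact ground
    truth for every signal class, plus Mann-Whitney and Holm-Sidak statistics.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    pracma,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
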