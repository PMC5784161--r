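Package: vitalrec
Title: Recording, Editing and Exporting Multi-Device Vital-Signs Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for time-synchronised multi-rate physiological
    data from anaesthesia devices. Provides a block-compressed container format
    for waveform (raw ADC counts plus conversion factors), numeric and event
    tracks; an automatic case-segmentation state machine driven by heart-rate
    and oxygen-saturation message presence; editing utilities (merge, trim,
    track removal); export to delimited tables and the European Data Format
    with interval resampling and missing-value policies; a plugin system for
    derived tracks with rolling-statistic built-ins; batch file utilities
    including timestamp-shifting de-identification; and a seeded simulator of
    anaesthesia-device message streams (ECG, plethysmography, pressures,
    capnography, EEG and slow numeric trends) with electrocautery-style gap
    injection for testing without hardware.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
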