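Package: emgconcord
Title: Device-Concordance Validation for Surface EMG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for statistically validating a prototype surface
    electromyography (EMG) acquisition device against a commercial
    reference system from synchronized dual-device recordings. Provides
    a seeded simulator of dual-device EMG sessions (shared band-limited
    muscle source, analog front-end model, amplitude-coded trigger
    channel), trigger-based epoching, the standard preprocessing chain
    (decimation to 500 Hz, 20-200 Hz Butterworth band-pass, peak
    normalization), a canonical set of 22 time-domain feature indices,
    an inverted mean-absolute-percentage-error (1 - MAPE) concordance
    statistic aggregated into feature-by-subject matrices, and
    temporal/spectrogram cross-correlation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
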