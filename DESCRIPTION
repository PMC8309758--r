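Package: accelalign
Title: Automated Temporal Alignment of Dual-Monitor Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Long-duration recordings from two independently clocked wearable
    accelerometers drift apart because each device's real-time clock has a
    small (ppm-level) frequency error.  accelalign estimates the initial clock
    offset and the linear clock drift between two triaxial acceleration
    streams from the acceleration itself: both streams are reduced to a
    rectified, band-passed ENMO movement signal, the time lag of hourly data
    blocks is found by normalized cross-correlation, a line is fitted to lag
    versus time with iterative standardized-residual outlier exclusion, and
    the secondary stream is finally resampled onto the reference timebase.
    Includes CSV and stereo-WAV input/output, a synthetic dual-channel
    generator with a ground-truth clock model, batch reporting, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
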