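Package: kidwatch
Title: Parturition Detection for Goats from Leg-Mounted Accelerometer Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting parturition (kidding) in goats from
    leg-mounted triaxial accelerometer streams. Simulates dual-rate sensor
    data with ground-truth behavior states and birth times, classifies
    per-record labor versus non-labor behavior with a decision tree (support
    vector machine comparison included), computes the Labor Pain Index
    (activity count times labor-classified count) over sliding time windows,
    selects the optimal window length by the central range value statistic,
    derives a three-sigma detection threshold, and raises early-warning
    events with a predicted first-birth time. Includes outlier filtering
    (range and Tukey-fence rules), information-gain feature ranking, a
    detection evaluation harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    rpart,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
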