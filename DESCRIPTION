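Package: cadgaze
Title: Eye-Tracking Analytics for CAD-Assisted Chest Radiograph Reading Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-reader crossover studies of computer-aided
    detection (CAD) prompt display on chest radiographs, quantified with eye
    tracking. Implements case allocation to a prescribed display operating
    point, five gaze metrics computed from raw 60 Hz gaze sample streams
    (interpretation time, lesion dwell time, time to first fixation,
    gaze-path length, buffered lung-field grid coverage), capture-ratio
    validity filtering with listwise pairing across sessions, diagnostic
    performance and prompt-adoption tabulation, and linear mixed models with
    crossed random intercepts for case and reader. A synthetic reader-study
    generator (lung masks, lesion and false-prompt boxes, gaze recordings
    with dropout, binary decisions) provides known ground truth for
    calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
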