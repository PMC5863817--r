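Package: vogcover
Title: Quantitative Ocular Deviation Measurement from Video-Oculography
    with Alternate Cover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Measures the angle of ocular deviation in comitant strabismus
    from video-oculography (VOG) recordings taken during an alternate cover
    test.  Provides a synthetic-data generator for model-eye calibration
    sessions and exotropic subject sessions, pupil-center detection in
    grayscale frames, segmentation of gaze traces by a cover schedule with
    per-cycle deviation extraction, model-eye linear calibration with
    degree/prism-diopter conversion, and the agreement-statistics battery
    (Bland-Altman limits of agreement, intraclass correlation, Pearson
    correlation, categorized differences) used to validate VOG against the
    alternate prism cover test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
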