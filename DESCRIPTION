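Package: clocksweep
Title: Clock-Sweep Lesion Brightness Radar and Reader-Study Signal Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies angular brightness irregularity of pigmented skin
    lesions with the "clock-sweep radar" statistic: mean intensity along the
    arm from lesion centroid to peripheral margin as a function of clock
    angle, summarized as brightness range divided by mean brightness, with
    annotated overlays marking the darkest, brightest and maximum-variation
    angles. Includes Otsu-based lesion segmentation, a synthetic lesion
    generator with analytic ground truth, an equal-variance signal-detection
    simulator for paired reader studies, and reader-study scoring
    (sensitivity, specificity, d-prime, matched-sample t-tests, paired ROC
    points) reproducing a published ten-reader melanoma versus nevus study
    summary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
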