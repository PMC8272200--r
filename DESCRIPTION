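Package: presscope
Title: Longitudinal In-Bed Pressure-Map Analysis for Pressure-Injury Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sequences of body-pressure maps recorded by
    sensor mattresses. Removes external-object artefacts (pillows, wedges) by
    Savitzky-Golay trend decomposition of unfolded pressure lines, enhances the
    cleaned frames, classifies the in-bed posture (supine, left lateral, right
    lateral) from histogram-of-oriented-gradients features, and detects, labels
    and tracks the high-risk body regions (head, shoulders, sacrum, feet) over
    time via gradient-field zero crossings. Includes a seeded synthetic-scene
    generator with full ground truth for validation, plain-text matrix I/O
    compatible with public pressure-mat datasets, and PSNR/RMSE quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    EBImage,
    kernlab,
    class,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    signal,
    optparse
Config/testthat/edition: 3
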