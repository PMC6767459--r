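Package: ecgrhythm
Title: Single-Lead ECG Denoising, Beat Detection and Rhythm Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for single-lead electrocardiograms recorded by
    portable home devices. Provides a four-stage noise-adequation bench
    (75 Hz low-pass, cubic-spline baseline removal, 50 Hz powerline notch,
    blockwise large-amplitude-noise exclusion), a tailored Pan-Tompkins
    QRS-complex detector built on a derivative feature filter, rhythm
    warnings (rhythm alterations, pauses), an atrial-fibrillation screen
    based on the occupancy of a discretized Lorenz-Poincare diagram of RR
    intervals against their first difference, time-domain heart-rate
    variability indices, and correlation-gated averaged beat templates for
    morphology inspection. A deterministic synthetic ECG generator with
    ground-truth annotations makes every stage testable without recorded
    patient data.
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
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
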